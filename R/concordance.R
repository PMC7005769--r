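#' Centered moving-average smoothing
#'
#' Smooths a per-residue profile with a centered moving average of odd
#' window width; windows are truncated at the ends of the sequence, and
#' `window = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param window Odd integer >= 1.
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0) abort("`window` must be an odd integer >= 1")
  if (window == 1) return(x)
  n <- length(x)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call threshold-crossing regions along a per-residue profile
#'
#' Smooths the profile with a centered moving average, finds maximal runs
#' of residues falling below (or above) the threshold, merges runs
#' separated by at most `merge_gap` non-qualifying residues, and discards
#' merged runs shorter than `min_len`. Each region's score is the mean of
#' the raw (unsmoothed) profile over the region.
#'
#' @param profile A tibble with a `residue_id` column (contiguous
#'   positions) and the value column named by `value`.
#' @param value Column holding the profile values (tidy-eval; default
#'   `longevity`).
#' @param direction `"below"` or `"above"`.
#' @param threshold Numeric threshold on the smoothed profile.
#' @param min_len Minimum region length in residues (>= 1).
#' @param merge_gap Maximum gap (residues) bridged when merging runs.
#' @param window Smoothing window (odd, >= 1) passed to
#'   [smooth_profile()].
#' @param kind Label recorded in the output `kind` column.
#' @param protein_id Identifier recorded in the output.
#' @return A region tibble (`protein_id`, `start`, `end`, `kind`,
#'   `score`) with 1-based inclusive residue coordinates; zero rows when
#'   nothing qualifies.
#' @examples
#' prof <- tibble::tibble(
#'   residue_id = 1:7,
#'   longevity = c(1, 1, 0.05, 0.05, 0.05, 1, 1)
#' )
#' call_regions(prof, direction = "below", threshold = 0.2, window = 1)
#' @export
call_regions <- function(profile, value = longevity,
                         direction = c("below", "above"), threshold,
                         min_len = 3, merge_gap = 2, window = 5,
                         kind = "region", protein_id = "protein") {
  direction <- match.arg(direction)
  if (min_len < 1) abort("`min_len` must be >= 1")
  if (merge_gap < 0) abort("`merge_gap` must be >= 0")
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  vcol <- as_name(enquo(value))
  raw <- profile[[vcol]]
  ids <- profile$residue_id
  sm <- smooth_profile(raw, window)
  qual <- if (direction == "below") sm < threshold else sm > threshold

  runs <- qualifying_runs(qual, merge_gap)
  runs <- runs[(runs$end - runs$start + 1L) >= min_len, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_regions())
  tibble::tibble(
    protein_id = protein_id,
    start = ids[runs$start],
    end = ids[runs$end],
    kind = kind,
    score = vapply(seq_len(nrow(runs)), function(i) {
      mean(raw[runs$start[i]:runs$end[i]])
    }, double(1))
  )
}

# maximal TRUE runs over positions, with runs separated by <= merge_gap
# FALSE positions merged; returns positional (index) start/end
qualifying_runs <- function(qual, merge_gap) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (length(idx) == 0) return(data.frame(start = integer(0), end = integer(0)))
  out_s <- starts[idx[1]]
  out_e <- ends[idx[1]]
  if (length(idx) > 1) {
    for (i in idx[-1]) {
      gap <- starts[i] - out_e[length(out_e)] - 1L
      if (gap <= merge_gap) {
        out_e[length(out_e)] <- ends[i]
      } else {
        out_s <- c(out_s, starts[i])
        out_e <- c(out_e, ends[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Consensus disorder regions across predictors
#'
#' Counts, per residue, how many disorder predictors score at or above the
#' disorder threshold, then calls regions where at least `k` predictors
#' agree. By default the count profile is not smoothed, so consensus
#' region boundaries are exact.
#'
#' @param disorder A long tibble with columns `predictor`, `residue_id`,
#'   `score` (as [sim_disorder()] returns), or a list of per-predictor
#'   tibbles with `residue_id` and `score`.
#' @param threshold Disorder-score threshold (default 0.5).
#' @param k Minimum number of agreeing predictors (`1 <= k <=`
#'   `n predictors`).
#' @param min_len,merge_gap,window,protein_id Passed to
#'   [call_regions()]; `window` defaults to 1 here.
#' @return A region tibble with kind `"disorder_consensus"`; the score is
#'   the mean predictor count over the region.
#' @export
disorder_consensus <- function(disorder, threshold = 0.5, k = 2,
                               min_len = 3, merge_gap = 2, window = 1,
                               protein_id = "protein") {
  if (is.data.frame(disorder)) {
    long <- disorder
  } else {
    long <- purrr::imap_dfr(disorder, function(d, nm) {
      tibble::tibble(
        predictor = as.character(nm),
        residue_id = d$residue_id,
        score = d$score
      )
    })
  }
  n_pred <- dplyr::n_distinct(long$predictor)
  if (!(k >= 1 && k <= n_pred)) {
    abort(sprintf("`k` must be between 1 and the %d predictors supplied", n_pred))
  }
  lens <- dplyr::count(long, .data$predictor)$n
  if (length(unique(lens)) != 1) abort("disorder profiles differ in length")
  counts <- long |>
    dplyr::group_by(.data$residue_id) |>
    dplyr::summarise(n_called = sum(.data$score >= threshold), .groups = "drop") |>
    dplyr::arrange(.data$residue_id)
  call_regions(
    counts, value = n_called, direction = "above", threshold = k - 0.5,
    min_len = min_len, merge_gap = merge_gap, window = window,
    kind = "disorder_consensus", protein_id = protein_id
  )
}

#' Flexible regions missed by every disorder predictor
#'
#' Flags low-longevity (flexible) regions whose overlap with every
#' disorder-consensus region is smaller than `min_overlap` residues —
#' regions where the simulation sees persistent structural fluctuation but
#' no disorder predictor raises a signal.
#'
#' @param low_longevity Region tibble of flexible regions (e.g.
#'   [call_regions()] on a longevity profile).
#' @param disorder Region tibble of disorder(-consensus) regions for the
#'   same protein.
#' @param min_overlap Minimum residue overlap (>= 1) for a disorder region
#'   to "cover" a flexible region.
#' @return The subset of `low_longevity` regions that no disorder region
#'   covers, relabelled with kind `"discordant"`.
#' @export
discordant_regions <- function(low_longevity, disorder, min_overlap = 1) {
  if (min_overlap < 1) abort("`min_overlap` must be >= 1")
  if (nrow(low_longevity) == 0) return(empty_regions())
  keep <- vapply(seq_len(nrow(low_longevity)), function(i) {
    if (nrow(disorder) == 0) return(TRUE)
    ov <- pmin(low_longevity$end[i], disorder$end) -
      pmax(low_longevity$start[i], disorder$start) + 1L
    all(ov < min_overlap)
  }, logical(1))
  out <- low_longevity[keep, , drop = FALSE]
  out$kind <- "discordant"
  out
}

#' Spearman rank correlation of two per-residue profiles
#'
#' Rank correlation with average ranks for ties. Zero variance in either
#' input leaves the correlation undefined and is an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation, in `[-1, 1]`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("rank correlation undefined: zero variance in an input")
  }
  cor(x, y, method = "spearman")
}

#' Residue-level Jaccard index between two region sets
#'
#' Expands each region set to its set of covered residue positions and
#' returns the size of the intersection over the size of the union. Both
#' sets empty gives 1 by convention.
#'
#' @param a,b Region tibbles (`start`, `end`, 1-based inclusive).
#' @return A number in `[0, 1]`.
#' @export
region_jaccard <- function(a, b) {
  expand <- function(r) {
    if (nrow(r) == 0) return(integer(0))
    unique(unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i])))
  }
  sa <- expand(a)
  sb <- expand(b)
  if (length(sa) == 0 && length(sb) == 0) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}
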