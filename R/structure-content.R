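#' Collapse eight-state labels to the three-state scheme
#'
#' Maps the DSSP eight-state alphabet to coil/helix/strand: the three
#' helix types (`H` alpha, `G` 3-10, `I` pi) become `H`; strands and
#' isolated beta bridges (`E`, `B`) become `E`; turns, bends, and coil
#' (`T`, `S`, `C`) become `C`.
#'
#' @param labels Character vector of Q8 codes (or a single string).
#' @return A character vector of Q3 codes of the same length.
#' @examples
#' q8_to_q3(c("G", "I", "H", "B", "E", "T", "S", "C"))
#' @export
q8_to_q3 <- function(labels) {
  labels <- split_labels(labels)
  check_q8(labels)
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "C", S = "C", C = "C")
  unname(map[labels])
}

#' Runs of consecutive ordered (helix or strand) residues
#'
#' Finds maximal runs of helix or strand residues after collapsing to the
#' three-state scheme, so that 3-10, alpha, and pi helix stretches
#' concatenate into a single helix run, and strands and bridges into a
#' single strand run.
#'
#' @param labels Character vector of Q8 codes (or a single string).
#' @return A tibble with columns `kind` (`"helix"` or `"beta"`) and
#'   `length` (residues), one row per ordered run in sequence order.
#' @export
ordered_runs <- function(labels) {
  q3 <- q8_to_q3(labels)
  r <- rle(q3)
  keep <- r$values %in% c("H", "E")
  tibble::tibble(
    kind = ifelse(r$values[keep] == "H", "helix", "beta"),
    length = r$lengths[keep]
  )
}

#' Helix/beta order score of a protein chain
#'
#' Quantifies a chain's structured content by summing an exponentially
#' increasing contribution `base^length` over every run of consecutive
#' helix or strand residues, then normalizing by the chain length. Long
#' uninterrupted structured stretches therefore dominate the score, and a
#' fully coiled chain scores zero. The coil fraction is reported alongside
#' as the complementary measure of disorder content.
#'
#' @param labels Character vector of Q8 codes (or a single string).
#' @param base Exponential base (> 1; default 2).
#' @param protein_id Identifier carried into the output.
#' @return A one-row tibble: `protein_id`, `length`, `n_runs`,
#'   `raw_score`, `normalized_score`, `coil_fraction`.
#' @examples
#' order_score("HHCEE")  # one helix run and one strand run
#' @export
order_score <- function(labels, base = 2, protein_id = NA_character_) {
  if (base <= 1) abort("`base` must be > 1")
  labels <- split_labels(labels)
  if (length(labels) == 0) abort("label string is empty")
  runs <- ordered_runs(labels)
  q3 <- q8_to_q3(labels)
  raw <- if (nrow(runs) == 0) 0 else sum(base^runs$length)
  tibble::tibble(
    protein_id = protein_id,
    length = length(labels),
    n_runs = nrow(runs),
    raw_score = raw,
    normalized_score = raw / length(labels),
    coil_fraction = mean(q3 == "C")
  )
}

#' Filter a protein set by chain length
#'
#' Keeps chains whose length lies within `center - tol` to `center + tol`
#' residues inclusive; the default window of 200 +/- 20 targets mid-sized
#' single-domain chains.
#'
#' @param refs A tibble with one row per protein and a `labels` (or
#'   `sequence`) column holding the per-residue string.
#' @param center,tol Window centre and half-width in residues (>= 0).
#' @return The filtered tibble.
#' @export
length_filter <- function(refs, center = 200, tol = 20) {
  if (center < 0 || tol < 0) abort("`center` and `tol` must be >= 0")
  col <- if ("labels" %in% names(refs)) "labels" else "sequence"
  if (!col %in% names(refs)) abort("`refs` needs a `labels` or `sequence` column")
  len <- nchar(refs[[col]])
  refs[len >= center - tol & len <= center + tol, , drop = FALSE]
}

#' Bin proteins by normalized order score
#'
#' Assigns each protein to one of `n_bins` bins of increasing helix/beta
#' content, either at the empirical quantiles of the normalized score
#' (default) or at user-supplied fixed edges. Scores equal to an edge fall
#' into the lower bin; bin 1 is the least ordered.
#'
#' @param scores A tibble with a `normalized_score` column (e.g. rows of
#'   [order_score()]).
#' @param n_bins Number of bins (>= 2).
#' @param mode `"quantile"` or `"fixed"`.
#' @param edges For `mode = "fixed"`: `n_bins - 1` strictly increasing
#'   thresholds.
#' @return `scores` with an added integer `bin` column; the edges used are
#'   attached as attribute `"bin_edges"`.
#' @export
assign_bins <- function(scores, n_bins = 5,
                        mode = c("quantile", "fixed"), edges = NULL) {
  mode <- match.arg(mode)
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  x <- scores$normalized_score
  if (mode == "quantile") {
    if (length(x) < n_bins) {
      abort(sprintf("%d proteins cannot fill %d quantile bins", length(x), n_bins))
    }
    edges <- unname(quantile(x, probs = seq_len(n_bins - 1) / n_bins))
    if (anyDuplicated(edges) || all(x == x[1])) {
      warn("tied normalized scores: quantile edges are not all distinct")
    }
  } else {
    if (is.null(edges) || length(edges) != n_bins - 1) {
      abort(sprintf("fixed mode needs %d edges", n_bins - 1))
    }
    if (is.unsorted(edges, strictly = TRUE)) abort("`edges` must be strictly increasing")
  }
  bin <- vapply(x, function(s) 1L + sum(s > edges), integer(1))
  out <- dplyr::mutate(scores, bin = bin)
  attr(out, "bin_edges") <- edges
  out
}
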