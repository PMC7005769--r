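#' Region-level concordance analysis for one protein
#'
#' Ties the per-residue profiles together: calls low-longevity (flexible)
#' bands on the longevity profile, low-confidence bands on the signed
#' predictor confidence, consensus regions across the disorder predictors,
#' and the discordant regions — flexible in simulation yet silent in the
#' disorder predictors. Pairwise Spearman correlations between the
#' profiles quantify the concordance the region calls visualize.
#'
#' @param longevity Longevity tibble from [longevity_profile()].
#' @param signed Optional signed-confidence tibble from
#'   [signed_confidence()].
#' @param disorder Optional long disorder tibble (`predictor`,
#'   `residue_id`, `score`).
#' @param rmsf Optional RMSF tibble from [rmsf_profile()].
#' @param protein_id Identifier used in region output.
#' @param longevity_threshold Smoothed-longevity threshold below which a
#'   residue counts as flexible (default 0.2).
#' @param conf_threshold Signed-confidence threshold below which a residue
#'   counts as poorly predicted (default 0, i.e. incorrect).
#' @param disorder_threshold,k Disorder-score threshold and minimum number
#'   of agreeing predictors for a consensus call (defaults 0.5 and 2).
#' @param min_len,merge_gap,window Region-calling parameters shared by all
#'   calls (defaults 3, 2, 5); the consensus count profile itself is not
#'   smoothed.
#' @param min_overlap Residue overlap below which a flexible region counts
#'   as missed by a disorder region (default 1).
#' @return An object of class `"concordance_analysis"`: a list with
#'   `regions` (one region tibble, all kinds), `correlations` (pairwise
#'   Spearman correlations), `profiles` (the joined per-residue table),
#'   `protein_id`, and `params`. Use [tidy()], [glance()], and
#'   [ggplot2::autoplot()] on it.
#' @export
concordance_analysis <- function(longevity, signed = NULL, disorder = NULL,
                                 rmsf = NULL, protein_id = "protein",
                                 longevity_threshold = 0.2,
                                 conf_threshold = 0,
                                 disorder_threshold = 0.5, k = 2,
                                 min_len = 3, merge_gap = 2, window = 5,
                                 min_overlap = 1) {
  profiles <- longevity[, c("residue_id", "longevity")]

  low_lon <- call_regions(
    longevity, value = longevity, direction = "below",
    threshold = longevity_threshold, min_len = min_len,
    merge_gap = merge_gap, window = window,
    kind = "low_longevity", protein_id = protein_id
  )
  regions <- low_lon
  cors <- tibble::tibble(pair = character(), rho = double())

  if (!is.null(signed)) {
    profiles <- dplyr::left_join(
      profiles, signed[, c("residue_id", "signed_conf")], by = "residue_id"
    )
    low_conf <- call_regions(
      signed, value = signed_conf, direction = "below",
      threshold = conf_threshold, min_len = min_len,
      merge_gap = merge_gap, window = window,
      kind = "low_confidence", protein_id = protein_id
    )
    regions <- dplyr::bind_rows(regions, low_conf)
    cors <- dplyr::bind_rows(cors, tibble::tibble(
      pair = "longevity~signed_conf",
      rho = spearman_rho(profiles$longevity, profiles$signed_conf)
    ))
  }

  if (!is.null(disorder)) {
    mean_dis <- disorder |>
      dplyr::group_by(.data$residue_id) |>
      dplyr::summarise(disorder_mean = mean(.data$score), .groups = "drop")
    profiles <- dplyr::left_join(profiles, mean_dis, by = "residue_id")
    consensus <- disorder_consensus(
      disorder, threshold = disorder_threshold, k = k,
      min_len = min_len, merge_gap = merge_gap, protein_id = protein_id
    )
    regions <- dplyr::bind_rows(regions, consensus)
    regions <- dplyr::bind_rows(
      regions, discordant_regions(low_lon, consensus, min_overlap = min_overlap)
    )
    cors <- dplyr::bind_rows(cors, tibble::tibble(
      pair = "longevity~disorder_mean",
      rho = spearman_rho(profiles$longevity, profiles$disorder_mean)
    ))
  }

  if (!is.null(rmsf)) {
    profiles <- dplyr::left_join(
      profiles, rmsf[, c("residue_id", "rmsf")], by = "residue_id"
    )
    cors <- dplyr::bind_rows(cors, tibble::tibble(
      pair = "longevity~rmsf",
      rho = spearman_rho(profiles$longevity, profiles$rmsf)
    ))
  }

  structure(
    list(
      regions = validate_regions(regions),
      correlations = cors,
      profiles = profiles,
      protein_id = protein_id,
      params = list(
        longevity_threshold = longevity_threshold,
        conf_threshold = conf_threshold,
        disorder_threshold = disorder_threshold, k = k,
        min_len = min_len, merge_gap = merge_gap, window = window,
        min_overlap = min_overlap
      )
    ),
    class = "concordance_analysis"
  )
}

#' @export
print.concordance_analysis <- function(x, ...) {
  cat(sprintf("<concordance_analysis: %s>\n", x$protein_id))
  cat(sprintf("  residues: %d\n", nrow(x$profiles)))
  counts <- table(x$regions$kind)
  for (k in names(counts)) cat(sprintf("  %s regions: %d\n", k, counts[[k]]))
  if (nrow(x$correlations) > 0) {
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  rho(%s) = %.3f\n",
                  x$correlations$pair[i], x$correlations$rho[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the regions of a concordance analysis
#'
#' @param x A [concordance_analysis()] object.
#' @param ... Unused.
#' @return The region tibble (`protein_id`, `start`, `end`, `kind`,
#'   `score`).
#' @method tidy concordance_analysis
#' @export
tidy.concordance_analysis <- function(x, ...) {
  x$regions
}

#' One-row summary of a concordance analysis
#'
#' @param x A [concordance_analysis()] object.
#' @param ... Unused.
#' @return A one-row tibble: residue count, region counts per kind, and
#'   the pairwise Spearman correlations (as `rho_*` columns).
#' @method glance concordance_analysis
#' @export
glance.concordance_analysis <- function(x, ...) {
  out <- tibble::tibble(
    protein_id = x$protein_id,
    n_residues = nrow(x$profiles)
  )
  for (kind in c("low_longevity", "low_confidence", "disorder_consensus", "discordant")) {
    out[[paste0("n_", kind)]] <- sum(x$regions$kind == kind)
  }
  if (nrow(x$correlations) > 0) {
    wide <- setNames(
      as.list(x$correlations$rho),
      paste0("rho_", sub("^longevity~", "", x$correlations$pair))
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(wide))
  }
  out
}
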