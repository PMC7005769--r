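pred_scheme <- function(pred) {
  if ("p_G" %in% names(pred)) "q8" else if ("p_C" %in% names(pred)) "q3" else
    abort("`pred` has no probability columns (p_<state>)")
}

pred_probs <- function(pred) {
  states <- if (pred_scheme(pred) == "q8") Q8_STATES else Q3_STATES
  as.matrix(pred[, paste0("p_", states), drop = FALSE])
}

ref_label_vector <- function(ref_labels) {
  if (is.data.frame(ref_labels)) ref_labels$label else split_labels(ref_labels)
}

#' Signed per-residue confidence of a structure prediction
#'
#' Scores each residue on a `[-1, 1]` scale: the magnitude is the maximum
#' class probability the predictor assigned at that residue, and the sign
#' records whether the predicted label matches the reference (positive)
#' or not (negative). Plotted along the sequence this exposes bands where
#' a predictor is wrong, or right but unsure. When the prediction is
#' three-state and the reference labels are eight-state, the reference is
#' collapsed with [q8_to_q3()] before comparison.
#'
#' @param pred A prediction tibble ([read_prediction_table()] or
#'   [sim_predictions()]).
#' @param ref_labels Reference secondary-structure labels: a character
#'   vector (or single string), or a reference tibble with a `label`
#'   column.
#' @return A tibble with columns `residue_id`, `label`, `ref_label`,
#'   `correct`, and `signed_conf`.
#' @export
signed_confidence <- function(pred, ref_labels) {
  ref <- ref_label_vector(ref_labels)
  if (length(ref) != nrow(pred)) {
    abort(sprintf(
      "prediction has %d residues but reference has %d",
      nrow(pred), length(ref)
    ))
  }
  scheme <- pred_scheme(pred)
  if (scheme == "q3") {
    ref <- q8_to_q3(ref)
  } else {
    check_q8(ref, "reference labels")
  }
  maxp <- apply(pred_probs(pred), 1, max)
  correct <- pred$label == ref
  tibble::tibble(
    residue_id = pred$residue_id,
    label = pred$label,
    ref_label = ref,
    correct = correct,
    signed_conf = ifelse(correct, maxp, -maxp)
  )
}

#' Per-protein prediction accuracy
#'
#' Fraction of residues whose predicted label matches the reference, with
#' positions lacking a reference label (`NA`) excluded from both numerator
#' and denominator.
#'
#' @inheritParams signed_confidence
#' @return A single number in `[0, 1]`.
#' @export
protein_accuracy <- function(pred, ref_labels) {
  ref <- ref_label_vector(ref_labels)
  if (length(ref) != nrow(pred)) {
    abort(sprintf(
      "prediction has %d residues but reference has %d",
      nrow(pred), length(ref)
    ))
  }
  keep <- !is.na(ref)
  if (!any(keep)) abort("no comparable residues (all reference labels missing)")
  if (pred_scheme(pred) == "q3") ref[keep] <- q8_to_q3(ref[keep])
  mean(pred$label[keep] == ref[keep])
}

#' Mean prediction accuracy per content bin with confidence intervals
#'
#' Averages per-protein accuracies within each bin of increasing
#' structured content and attaches a two-sided Student-t confidence
#' interval on the mean (clipped to `[0, 1]` for reporting). Bins with a
#' single protein get an undefined (`NA`) interval and a warning.
#'
#' @param accuracies A tibble with columns `bin` (integer) and `accuracy`
#'   (per-protein fraction), e.g. [assign_bins()] output joined with
#'   [protein_accuracy()] values.
#' @param ci_level Confidence level in `(0, 1)`; default 0.95.
#' @return A tibble with one row per bin, in increasing bin order:
#'   `bin`, `n`, `mean_accuracy`, `ci_low`, `ci_high`, `ci_level`.
#' @export
bin_accuracy <- function(accuracies, ci_level = 0.95) {
  if (!(ci_level > 0 && ci_level < 1)) abort("`ci_level` must be in (0, 1)")
  out <- accuracies |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd = stats::sd(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin)
  half <- rep(NA_real_, nrow(out))
  multi <- out$n > 1
  half[multi] <- qt(1 - (1 - ci_level) / 2, df = out$n[multi] - 1) *
    out$sd[multi] / sqrt(out$n[multi])
  if (any(out$n == 1)) {
    warn("bin(s) with a single protein: confidence interval undefined there")
  }
  out$ci_low <- pmax(out$mean_accuracy - half, 0)
  out$ci_high <- pmin(out$mean_accuracy + half, 1)
  out$ci_level <- ci_level
  out$sd <- NULL
  out
}
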