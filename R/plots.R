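#' Plot the per-residue profiles and called regions of an analysis
#'
#' Draws each available per-residue profile (longevity, signed predictor
#' confidence, mean disorder score, RMSF) as a facet along the sequence,
#' with the called regions shaded by kind.
#'
#' @param object A [concordance_analysis()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_analysis
#' @export
autoplot.concordance_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$profiles, -"residue_id",
    names_to = "profile", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$residue_id, y = .data$value))
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(
        xmin = .data$start - 0.5, xmax = .data$end + 0.5,
        ymin = -Inf, ymax = Inf, fill = .data$kind
      ),
      alpha = 0.25, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$profile), scales = "free_y") +
    ggplot2::labs(
      x = "residue", y = NULL, fill = "region",
      title = object$protein_id
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-residue longevity profile
#'
#' @param longevity Tibble from [longevity_profile()].
#' @param regions Optional region tibble to shade.
#' @return A ggplot object.
#' @export
plot_longevity <- function(longevity, regions = NULL) {
  p <- ggplot2::ggplot(
    longevity, ggplot2::aes(x = .data$residue_id, y = .data$longevity)
  )
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(
        xmin = .data$start - 0.5, xmax = .data$end + 0.5,
        ymin = -Inf, ymax = Inf, fill = .data$kind
      ),
      alpha = 0.25, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "structural longevity", fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot mean prediction accuracy per content bin
#'
#' Point-and-errorbar display of [bin_accuracy()] output: per-bin mean
#' accuracy with its confidence interval, bins ordered by increasing
#' structured content.
#'
#' @param summary Tibble from [bin_accuracy()].
#' @return A ggplot object.
#' @export
plot_bin_accuracy <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data$bin), y = .data$mean_accuracy)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2
    ) +
    ggplot2::labs(
      x = "content bin (increasing helix/beta content)",
      y = "mean prediction accuracy"
    ) +
    ggplot2::theme_minimal()
}
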