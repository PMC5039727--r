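#' Plot a fitted acceptance curve
#'
#' Shows the data points the curve was fitted to (when available), the
#' fitted logistic acceptance curve, and a dashed vertical line at the
#' offer-independent demand threshold.
#'
#' @param object An `ug_logistic`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ug_logistic
#' @export
autoplot.ug_logistic <- function(object, ...) {
  curve <- payoff_curve(object, seq(0, 1, by = 0.005))
  d <- demand_threshold(object)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$offer)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$acceptance)) +
    ggplot2::geom_vline(xintercept = d, linetype = "dashed") +
    ggplot2::labs(x = "offer", y = "acceptance probability",
                  title = sprintf("k = %.3g, X0 = %.3g, demand = %.2f",
                                  object$k, object$X0, d)) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$offer, y = .data$rate))
  }
  p
}

#' Plot per-generation locus means of a run
#'
#' @param object An `ug_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ug_run
#' @export
autoplot.ug_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = -"generation",
                              names_to = "locus", values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$mean,
                                     colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "generation", y = "population mean") +
    ggplot2::theme_minimal()
}

#' Plot a sweep summary
#'
#' Grand-mean evolved loci (with standard-error bars) against selection
#' strength, one line per locus, faceted by mode.
#'
#' @param summary A long-form `RunSummary` tibble from [run_sweep()] /
#'   [aggregate_summary()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(summary) {
  stopifnot(all(c("mode", "w", "locus", "mean", "se") %in% names(summary)))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$w, y = .data$mean,
                               colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "selection strength w", y = "grand-mean LOD value") +
    ggplot2::theme_minimal()
}

#' Plot a recognition-threshold histogram
#'
#' @param distribution A tibble from [threshold_distribution()].
#' @return A ggplot object.
#' @export
plot_threshold_distribution <- function(distribution) {
  stopifnot(all(c("midpoint", "count") %in% names(distribution)))
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = (distribution$upper - distribution$lower)[1],
                      fill = "grey40") +
    ggplot2::labs(x = "recognition threshold", y = "pooled LOD count") +
    ggplot2::theme_minimal()
}
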