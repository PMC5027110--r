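# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_hline
#'   geom_raster geom_col geom_histogram facet_wrap labs scale_fill_gradient2
#' @export
ggplot2::autoplot

#' Plot a conditional odds-ratio curve
#'
#' Odds ratio of a one-SD increase in gene A as a function of gene-B
#' expression, with the resample percentile band when present; the red line
#' marks OR = 1.
#'
#' @param object An [or_curve()] or [or_band()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.or_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$b, y = .data$or))
  if (all(c("lo", "hi") %in% names(object))) {
    p <- p + geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80", alpha = 0.7)
  }
  p + geom_line() +
    geom_hline(yintercept = 1, colour = "red", linetype = 2) +
    labs(x = attr(object, "feature_b") %||% "gene B expression (SD units)",
         y = "odds ratio per SD of gene A")
}

#' Plot a log-odds surface
#'
#' Heatmap of the fitted linear predictor over the two-gene expression
#' grid; the saddle curvature is the interaction coefficient.
#'
#' @param object A [log_odds_surface()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.log_odds_surface <- function(object, ...) {
  ggplot(object, aes(x = .data$a, y = .data$b, fill = .data$log_odds)) +
    geom_raster() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = attr(object, "feature_a") %||% "gene A",
         y = attr(object, "feature_b") %||% "gene B",
         fill = "log-odds")
}

#' Plot resampled p-value distributions
#'
#' One histogram per model term across resamples; a right-skewed pile-up
#' near zero marks terms informative of the outcome.
#'
#' @param object A [clr_bootstrap()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.resample_summary <- function(object, bins = 20, ...) {
  long <- as_tibble(object$p) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "term", values_to = "p")
  ggplot(long, aes(x = .data$p)) +
    geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    facet_wrap(~term) +
    labs(x = "Wald p-value across resamples", y = "resamples")
}

#' Plot a consensus frequency matrix
#'
#' @param object A [consensus()] result.
#' @param ... Unused.
#' @return A ggplot heatmap of edge frequencies.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_network <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$feature_a, y = .data$feature_b,
               fill = .data$frequency)) +
    geom_raster() +
    scale_fill_gradient2(low = "white", mid = "steelblue",
                         high = "firebrick", midpoint = 0.5,
                         limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "consensus\nfrequency")
}
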