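# broom methods for the package's fitted objects.

#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' Tidy a fitted logistic model
#'
#' @param x A `coexpair_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std_error`,
#'   `p_value`.
#' @exportS3Method broom::tidy
tidy.coexpair_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a fitted logistic model
#'
#' @param x A `coexpair_fit`.
#' @param ... Unused.
#' @return Tibble with `model_tag`, `features`, `n_used`, `n_dropped`,
#'   `converged`, `deviance`.
#' @exportS3Method broom::glance
glance.coexpair_fit <- function(x, ...) {
  tibble(model_tag = x$model_tag,
         features = paste(x$features, collapse = "|"),
         n_used = x$n_used, n_dropped = x$n_dropped,
         converged = x$converged, deviance = x$deviance)
}

#' @export
print.coexpair_fit <- function(x, ...) {
  cat("Logistic fit (", x$model_tag, "): ",
      paste(x$features, collapse = " | "), "\n",
      "  n = ", x$n_used, if (!x$converged) "  [NOT CONVERGED]" else "",
      "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy a resample summary
#'
#' @param x A `resample_summary`.
#' @param ... Unused.
#' @return One row per term: `term`, `fraction_significant`, `median_p`,
#'   `mean_estimate`.
#' @exportS3Method broom::tidy
tidy.resample_summary <- function(x, ...) {
  x$summary
}

#' One-row summary of a resample run
#'
#' @param x A `resample_summary`.
#' @param ... Unused.
#' @exportS3Method broom::glance
glance.resample_summary <- function(x, ...) {
  tibble(model_tag = x$model_tag,
         features = paste(x$features, collapse = "|"),
         n_resamples = x$n_resamples, alpha = x$alpha,
         controls_per_case = x$controls_per_case)
}

#' Tidy a pair screen
#'
#' @param x A `pair_screen`.
#' @param ... Unused.
#' @return The per-pair classification tibble.
#' @exportS3Method broom::tidy
tidy.pair_screen <- function(x, ...) {
  x$pairs
}

#' One-row summary of a pair screen
#'
#' @param x A `pair_screen`.
#' @param ... Unused.
#' @exportS3Method broom::glance
glance.pair_screen <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, alpha = x$alpha,
         n_interacting = sum(x$pairs$interaction_sig),
         n_gene_pairs = dplyr::n_distinct(
           pair_key(x$pairs$gene_a[x$pairs$interaction_sig],
                    x$pairs$gene_b[x$pairs$interaction_sig])))
}

#' Tidy a consensus network into a long edge table
#'
#' @param x A `consensus_network`.
#' @param ... Unused.
#' @return One row per unordered feature pair: `feature_a`, `feature_b`,
#'   `frequency`.
#' @exportS3Method broom::tidy
tidy.consensus_network <- function(x, ...) {
  ut <- which(upper.tri(x$M), arr.ind = TRUE)
  tibble(feature_a = rownames(x$M)[ut[, 1]],
         feature_b = colnames(x$M)[ut[, 2]],
         frequency = x$M[ut]) |>
    arrange(.data$feature_a, .data$feature_b)
}

#' One-row summary of a consensus network
#'
#' @param x A `consensus_network`.
#' @param ... Unused.
#' @exportS3Method broom::glance
glance.consensus_network <- function(x, ...) {
  up <- x$M[upper.tri(x$M)]
  tibble(n_features = length(x$features), k = x$k,
         subsample_size = x$subsample_size, alpha = x$alpha,
         n_bins = x$n_bins,
         frac_observed = mean(up > 0),
         max_frequency = if (length(up)) max(up) else NA_real_)
}
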