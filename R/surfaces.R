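# Conditional odds-ratio curves and log-odds surfaces for interacting pairs.
#
# For the interactive pair model logit(P) = b0 + bA*a + bB*b + bAB*ab + cov,
# the odds ratio of a one-SD increase in gene A at gene-B expression b is
# closed form: OR(b) = exp(sd_A * (bA + bAB * b)); every covariate term
# cancels in the ratio. Its log is affine in b, crossing OR = 1 at
# b = -bA / bAB.

get_coef <- function(fit, term) {
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("term not in fit: ", term, call. = FALSE)
  fit$terms$estimate[i]
}

default_grid <- function(fit, feature, n_grid = 101) {
  fs <- fit$feature_summary
  i <- match(feature, fs$feature)
  # grid on the scale the model was fitted on (z-scores when standardized)
  q <- if (isTRUE(fit$standardized)) {
    c((fs$q01[i] - fs$mean[i]) / fs$sd[i], (fs$q99[i] - fs$mean[i]) / fs$sd[i])
  } else {
    c(fs$q01[i], fs$q99[i])
  }
  seq(q[1], q[2], length.out = n_grid)
}

#' Conditional odds-ratio curve for an interacting pair
#'
#' Computes `OR(b) = odds(a + sd_a, b) / odds(a, b)` for a fitted
#' interactive pair model as a function of gene-B expression `b`, using the
#' closed form `exp(sd_a * (beta_A + beta_AB * b))`. Covariates cancel in
#' the ratio, so no reference values are needed.
#'
#' @param fit A converged `coexpair_fit` with `model_tag = "pair_interactive"`
#'   (gene A is the first fitted feature).
#' @param sd_a Standard-deviation step for gene A on the fitted scale
#'   (1 when expression was z-scored before fitting, the default).
#' @param grid_b Gene-B expression grid; defaults to 101 points spanning the
#'   empirical 1st-99th percentile of gene B on the fitted scale.
#' @param n_grid Grid size when `grid_b` is `NULL`.
#' @return An `or_curve` tibble with columns `b`, `or`, and attributes
#'   `beta_a`, `beta_ab`, `sd_a`, and `root` (the `b` where OR = 1, `NA`
#'   when the interaction is zero).
#' @export
or_curve <- function(fit, sd_a = 1, grid_b = NULL, n_grid = 101) {
  stopifnot(inherits(fit, "coexpair_fit"))
  if (fit$model_tag != "pair_interactive") {
    stop("or_curve needs an interactive pair fit", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  a <- fit$features[1]; b <- fit$features[2]
  beta_a <- get_coef(fit, a)
  beta_ab <- get_coef(fit, paste0(a, ":", b))
  grid_b <- grid_b %||% default_grid(fit, b, n_grid)
  out <- tibble(b = grid_b, or = exp(sd_a * (beta_a + beta_ab * grid_b)))
  structure(out, class = c("or_curve", class(out)),
            beta_a = beta_a, beta_ab = beta_ab, sd_a = sd_a,
            feature_a = a, feature_b = b,
            root = if (beta_ab != 0) -beta_a / beta_ab else NA_real_)
}

#' Odds-ratio curve with resample percentile band
#'
#' Evaluates one odds-ratio curve per resampled coefficient pair and
#' summarizes them pointwise by the 2.5th, 50th and 97.5th percentiles,
#' reproducing resample bands around the conditional odds ratio.
#'
#' @param coefs A [clr_bootstrap()] result for an interactive pair, or a
#'   tibble/matrix with columns `beta_a` and `beta_ab` (one row per
#'   resample).
#' @param sd_a SD step for gene A on the fitted scale.
#' @param grid_b Gene-B expression grid.
#' @return An `or_curve` tibble with columns `b`, `or` (median), `lo`, `hi`,
#'   and attribute `curves` (resamples x grid matrix).
#' @export
or_band <- function(coefs, sd_a = 1, grid_b = seq(-3, 3, length.out = 101)) {
  if (inherits(coefs, "resample_summary")) {
    if (coefs$model_tag != "pair_interactive") {
      stop("resample summary must be for an interactive pair", call. = FALSE)
    }
    est <- coefs$estimates
    coefs <- tibble(beta_a = est[, 1], beta_ab = est[, 3])
  }
  coefs <- as_tibble(as.data.frame(coefs))
  stopifnot(all(c("beta_a", "beta_ab") %in% names(coefs)))
  coefs <- coefs |> filter(is.finite(.data$beta_a), is.finite(.data$beta_ab))
  if (nrow(coefs) < 1) stop("no finite resample coefficients", call. = FALSE)
  curves <- exp(sd_a * outer(coefs$beta_a, rep(1, length(grid_b))) +
                  sd_a * outer(coefs$beta_ab, grid_b))
  qs <- apply(curves, 2, stats::quantile, c(0.025, 0.5, 0.975))
  out <- tibble(b = grid_b, or = qs[2, ], lo = qs[1, ], hi = qs[3, ])
  structure(out, class = c("or_curve", class(out)),
            sd_a = sd_a, curves = curves)
}

#' Log-odds surface over a two-gene expression grid
#'
#' Evaluates the fitted linear predictor
#' \eqn{\eta(a, b) = \eta_0 + \beta_A a + \beta_B b + \beta_{AB} ab} on a
#' grid, with covariates fixed at their reference values (mean for
#' continuous, mode for categorical). The mixed second difference over any
#' 2x2 sub-grid equals `beta_AB * da * db`; its sign classifies the saddle.
#'
#' @inheritParams or_curve
#' @param grid_a,grid_b Expression grids for the two genes (defaults as in
#'   [or_curve()]).
#' @param covariate_values Optional named list overriding reference
#'   covariate values.
#' @return A `log_odds_surface` tibble with columns `a`, `b`, `log_odds`
#'   and attributes `beta_ab` and `eta0`.
#' @export
log_odds_surface <- function(fit, grid_a = NULL, grid_b = NULL, n_grid = 101,
                             covariate_values = NULL) {
  stopifnot(inherits(fit, "coexpair_fit"))
  if (fit$model_tag != "pair_interactive") {
    stop("log_odds_surface needs an interactive pair fit", call. = FALSE)
  }
  a <- fit$features[1]; b <- fit$features[2]
  beta_a <- get_coef(fit, a)
  beta_b <- get_coef(fit, b)
  beta_ab <- get_coef(fit, paste0(a, ":", b))
  grid_a <- grid_a %||% default_grid(fit, a, n_grid)
  grid_b <- grid_b %||% default_grid(fit, b, n_grid)
  # baseline eta at a = b = 0 with covariates at reference values
  if (is.null(fit$glm)) {
    eta0 <- get_coef(fit, "(Intercept)")
    grid <- tidyr::expand_grid(a = grid_a, b = grid_b)
    out <- grid |>
      mutate(log_odds = eta0 + beta_a * .data$a + beta_b * .data$b +
               beta_ab * .data$a * .data$b)
    return(structure(out, class = c("log_odds_surface", class(out)),
                     beta_ab = beta_ab, eta0 = eta0,
                     feature_a = a, feature_b = b))
  }
  mf <- fit$glm$model
  new <- mf[1, , drop = FALSE]
  for (nm in names(new)) {
    v <- mf[[nm]]
    if (is.factor(v)) {
      new[[nm]] <- factor(names(which.max(table(v))), levels = levels(v))
    } else {
      new[[nm]] <- mean(v)
    }
  }
  for (nm in names(fit$term_map)) if (nm %in% names(new)) new[[nm]] <- 0
  if (!is.null(covariate_values)) {
    for (nm in names(covariate_values)) {
      new[[nm]] <- if (is.factor(mf[[nm]])) {
        factor(covariate_values[[nm]], levels = levels(mf[[nm]]))
      } else covariate_values[[nm]]
    }
  }
  eta0 <- unname(stats::predict(fit$glm, newdata = new, type = "link"))
  grid <- tidyr::expand_grid(a = grid_a, b = grid_b)
  out <- grid |>
    mutate(log_odds = eta0 + beta_a * .data$a + beta_b * .data$b +
             beta_ab * .data$a * .data$b)
  structure(out, class = c("log_odds_surface", class(out)),
            beta_ab = beta_ab, eta0 = eta0,
            feature_a = a, feature_b = b)
}

#' Binned expression histogram to accompany odds-ratio curves
#'
#' @param expr Expression tibble.
#' @param feature Feature to bin.
#' @param breaks Number of bins (passed to [graphics::hist()] logic via
#'   [base::cut()]) or a vector of break points.
#' @param standardize Bin the z-scored values (to match fitted-scale grids).
#' @return Tibble with `mid`, `count`.
#' @export
expression_histogram <- function(expr, feature, breaks = 30, standardize = TRUE) {
  v <- expr[[feature]]
  if (standardize) v <- as.numeric(scale(v))
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble(mid = h$mids, count = h$counts)
}
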