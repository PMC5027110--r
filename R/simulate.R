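# Synthetic cohorts and count matrices with known ground truth.
#
# Three generators mirror the three data regimes the analysis runs on:
# an unmatched case-control cohort with continuous expression and a logistic
# outcome model (main + product-interaction effects), a family-structured
# population cohort with rare cases for matched designs, and RNA-seq-like
# negative-binomial count matrices with planted dependency motifs for
# network inference.

#' Ground truth for a simulated case-control cohort
#'
#' Bundles the generative parameters of the logistic outcome model
#' \eqn{logit(P(case)) = \beta_0 + \sum_i \beta_i x_i + \sum_{ij} \beta_{ij}
#' x_i x_j + covariate\ terms}, together with the correlation structure of
#' the (unit-variance) log-expression features.
#'
#' @param features Character vector of feature identifiers.
#' @param beta0 Intercept on the logit scale. The default of -1 gives a case
#'   fraction near 0.27 under the null, comparable to a catheterization
#'   cohort enriched for cases.
#' @param beta_main Named numeric vector of main-effect coefficients (per SD
#'   of expression); features not named get 0.
#' @param beta_pair Tibble with columns `feature_a`, `feature_b`, `beta`
#'   giving product-interaction coefficients for unordered pairs.
#' @param covariate_effects Named numeric vector with elements `age`
#'   (per year, age centered), `sex` (indicator of second sex level), `race`
#'   (indicator of non-reference race).
#' @param expression_cor Feature correlation matrix (symmetric positive
#'   semi-definite, unit diagonal); identity when `NULL`.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(features,
                         beta0 = -1,
                         beta_main = NULL,
                         beta_pair = NULL,
                         covariate_effects = c(age = 0.02, sex = 0.4, race = 0.2),
                         expression_cor = NULL) {
  features <- as.character(features)
  m <- length(features)
  if (anyDuplicated(features)) stop("duplicated features", call. = FALSE)
  bm <- stats::setNames(numeric(m), features)
  if (!is.null(beta_main)) {
    if (is.null(names(beta_main)) || !all(names(beta_main) %in% features)) {
      stop("beta_main must be named by features", call. = FALSE)
    }
    bm[names(beta_main)] <- beta_main
  }
  if (is.null(beta_pair)) {
    beta_pair <- tibble(feature_a = character(), feature_b = character(), beta = numeric())
  } else {
    beta_pair <- as_tibble(beta_pair)
    stopifnot(all(c("feature_a", "feature_b", "beta") %in% names(beta_pair)))
    if (!all(c(beta_pair$feature_a, beta_pair$feature_b) %in% features)) {
      stop("beta_pair references unknown features", call. = FALSE)
    }
    ka <- pmin(beta_pair$feature_a, beta_pair$feature_b)
    kb <- pmax(beta_pair$feature_a, beta_pair$feature_b)
    beta_pair$feature_a <- ka
    beta_pair$feature_b <- kb
    if (anyDuplicated(pair_key(ka, kb))) stop("duplicated pair in beta_pair", call. = FALSE)
  }
  if (is.null(expression_cor)) {
    expression_cor <- diag(m)
  } else {
    expression_cor <- as.matrix(expression_cor)
    if (!isTRUE(all.equal(expression_cor, t(expression_cor), tolerance = 1e-10))) {
      stop("expression_cor must be symmetric", call. = FALSE)
    }
    ev <- eigen(expression_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("expression_cor is not positive semi-definite", call. = FALSE)
  }
  dimnames(expression_cor) <- list(features, features)
  structure(list(features = features, beta0 = beta0, beta_main = bm,
                 beta_pair = beta_pair, covariate_effects = covariate_effects,
                 expression_cor = expression_cor),
            class = "cohort_truth")
}

# Draw n x m standardized multivariate-normal expression given a correlation
# matrix (eigen square root handles PSD-but-singular cases).
draw_expression <- function(n, cor_mat) {
  m <- ncol(cor_mat)
  e <- eigen(cor_mat, symmetric = TRUE)
  rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m) %*% t(e$vectors)
  z <- matrix(stats::rnorm(n * m), n, m) %*% rt
  colnames(z) <- colnames(cor_mat)
  z
}

linear_predictor <- function(z, truth, age, sex_ind, race_ind, age_center) {
  eta <- rep(truth$beta0, nrow(z))
  eta <- eta + drop(z %*% truth$beta_main[colnames(z)])
  if (nrow(truth$beta_pair)) {
    for (r in seq_len(nrow(truth$beta_pair))) {
      eta <- eta + truth$beta_pair$beta[r] *
        z[, truth$beta_pair$feature_a[r]] * z[, truth$beta_pair$feature_b[r]]
    }
  }
  ce <- truth$covariate_effects
  if (!is.na(ce["age"])) eta <- eta + ce[["age"]] * (age - age_center)
  if (!is.na(ce["sex"])) eta <- eta + ce[["sex"]] * sex_ind
  if (!is.na(ce["race"])) eta <- eta + ce[["race"]] * race_ind
  eta
}

#' Simulate an unmatched case-control cohort
#'
#' Generates standardized multivariate-normal log-expression with the
#' correlation structure in `truth`, covariates (age uniform over
#' `age_range`, categorical sex and race at the given frequencies), and a
#' Bernoulli outcome from the logistic model in `truth`. Identical seeds
#' give identical output.
#'
#' @param n Number of samples (at least 10).
#' @param truth A [cohort_truth()] object.
#' @param seed Integer seed; every generator here is a deterministic
#'   function of (parameters, seed).
#' @param age_range Two-element numeric range for uniform ages, in years.
#' @param sex_levels,sex_prob Categories and sampling frequencies for sex.
#' @param race_levels,race_prob Categories and sampling frequencies for race.
#' @return A list with elements `expression` (tibble, `sample_id` + one
#'   column per feature), `annotations` (tibble with `sample_id`, `outcome`,
#'   `age`, `sex`, `race`), and `truth`.
#' @export
simulate_cohort <- function(n, truth, seed,
                            age_range = c(40, 80),
                            sex_levels = c("F", "M"), sex_prob = c(0.5, 0.5),
                            race_levels = c("W", "B", "O"),
                            race_prob = c(0.8, 0.15, 0.05)) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  local_seed(seed, {
    z <- draw_expression(n, truth$expression_cor)
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- sample(sex_levels, n, replace = TRUE, prob = sex_prob)
    race <- sample(race_levels, n, replace = TRUE, prob = race_prob)
    eta <- linear_predictor(z, truth, age,
                            as.numeric(sex == sex_levels[2]),
                            as.numeric(race != race_levels[1]),
                            mean(age_range))
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    ids <- sprintf("S%05d", seq_len(n))
    list(
      expression = tibble(sample_id = ids) |>
        dplyr::bind_cols(as_tibble(z, .name_repair = "minimal")),
      annotations = tibble(sample_id = ids, outcome = as.integer(y),
                           age = age, sex = sex, race = race),
      truth = truth
    )
  })
}

#' Simulate a family-structured population cohort for matched designs
#'
#' Emulates a population cohort with extended families and a low case rate,
#' the regime in which matched case-control resampling is used. A shared
#' Gaussian intercept per family is added to every expression feature;
#' the outcome follows the logistic model in `truth` with intercept shifted
#' so the marginal case rate is near `case_rate`. Ages are redrawn (bounded
#' retries) until every case has at least one eligible control -- same sex,
#' age within `age_window` years, different family.
#'
#' @param n_families Number of families.
#' @param family_size Members per family.
#' @param case_rate Target marginal case probability (small).
#' @param truth A [cohort_truth()] object; its `beta0` is replaced by
#'   `qlogis(case_rate)`.
#' @param seed Integer seed.
#' @param family_sd SD of the shared per-family expression intercept.
#' @param age_range Uniform age range in years.
#' @param age_window Matching window used for the eligibility guarantee.
#' @param max_retries Age redraw attempts before giving up.
#' @return A list with `expression`, `annotations` (including `family_id`),
#'   and `truth`.
#' @export
simulate_family_cohort <- function(n_families, family_size, case_rate, truth,
                                   seed, family_sd = 0.3,
                                   age_range = c(40, 80), age_window = 2,
                                   max_retries = 20) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (case_rate <= 0 || case_rate >= 0.5) {
    stop("case_rate must be in (0, 0.5): matched designs target rare cases", call. = FALSE)
  }
  n <- n_families * family_size
  local_seed(seed, {
    fam <- rep(sprintf("F%04d", seq_len(n_families)), each = family_size)
    z <- draw_expression(n, truth$expression_cor)
    u <- stats::rnorm(n_families, 0, family_sd)
    z <- z + u[rep(seq_len(n_families), each = family_size)]
    sex <- sample(c("F", "M"), n, replace = TRUE)
    truth2 <- truth
    truth2$beta0 <- stats::qlogis(case_rate)
    eligible_ok <- function(age, y) {
      cases <- which(y == 1)
      if (!length(cases)) return(TRUE)
      all(vapply(cases, function(i) {
        any(y == 0 & abs(age - age[i]) <= age_window & sex == sex[i] & fam != fam[i])
      }, logical(1)))
    }
    age <- y <- NULL
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      age <- stats::runif(n, age_range[1], age_range[2])
      eta <- linear_predictor(z, truth2, age, as.numeric(sex == "M"), 0,
                              mean(age_range))
      y <- stats::rbinom(n, 1, stats::plogis(eta))
      if (eligible_ok(age, y)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not satisfy match eligibility after retries; use a larger cohort",
           call. = FALSE)
    }
    ids <- sprintf("S%05d", seq_len(n))
    list(
      expression = tibble(sample_id = ids) |>
        dplyr::bind_cols(as_tibble(z, .name_repair = "minimal")),
      annotations = tibble(sample_id = ids, outcome = as.integer(y),
                           age = age, sex = sex, family_id = fam),
      truth = truth2
    )
  })
}

#' Ground truth for a simulated count matrix with planted dependencies
#'
#' Describes the latent dependency structure of an RNA-seq-like count
#' matrix: motifs (`chain`, `triangle`, `latent_factor`) over named
#' transcripts, independent background transcripts, negative-binomial
#' overdispersion, per-transcript zero inflation, and an optional block of
#' poorly expressed transcripts that fail the non-zero-fraction filter.
#'
#' @param motifs List of motifs; each is `list(kind =, features =, strength =)`
#'   with `kind` one of `"chain"`, `"triangle"`, `"latent_factor"` and
#'   `strength` the latent correlation (chain: per link; triangle:
#'   equicorrelation; latent_factor: loading).
#' @param n_background Number of independent background transcripts.
#' @param dispersion Negative-binomial overdispersion (variance
#'   \eqn{\mu + dispersion\,\mu^2}).
#' @param zero_fraction Zero-inflation probability applied to every
#'   regular transcript.
#' @param n_low Number of poorly expressed transcripts.
#' @param low_zero_fraction Zero-inflation for the poorly expressed block
#'   (default 0.5, which fails a 65% non-zero filter by construction).
#' @param log_mean,latent_scale Log-scale mean and latent effect size of
#'   counts.
#' @return An object of class `network_truth` with a `direct_edges` tibble
#'   (columns `feature_a`, `feature_b`, `kind`).
#' @export
network_truth <- function(motifs = list(),
                          n_background = 0, dispersion = 0.5,
                          zero_fraction = 0, n_low = 0,
                          low_zero_fraction = 0.5,
                          log_mean = 3, latent_scale = 1) {
  stopifnot(zero_fraction >= 0, zero_fraction <= 1,
            low_zero_fraction >= 0, low_zero_fraction <= 1,
            dispersion >= 0)
  feats <- character()
  edges <- list()
  for (mo in motifs) {
    stopifnot(mo$kind %in% c("chain", "triangle", "latent_factor"))
    f <- as.character(mo$features)
    if (mo$kind == "chain" && length(f) < 2) stop("chain needs >= 2 features", call. = FALSE)
    if (mo$kind == "triangle" && length(f) != 3) stop("triangle needs 3 features", call. = FALSE)
    feats <- c(feats, f)
    e <- switch(mo$kind,
      chain = tibble(feature_a = f[-length(f)], feature_b = f[-1]),
      triangle = enumerate_pairs(f),
      latent_factor = enumerate_pairs(f)
    )
    e$kind <- mo$kind
    edges[[length(edges) + 1]] <- e
  }
  if (anyDuplicated(feats)) stop("features shared across motifs are not supported", call. = FALSE)
  bg <- if (n_background > 0) sprintf("BG%03d", seq_len(n_background)) else character()
  low <- if (n_low > 0) sprintf("LOW%03d", seq_len(n_low)) else character()
  structure(list(motifs = motifs,
                 features = c(feats, bg, low),
                 background = bg, low_expressed = low,
                 direct_edges = if (length(edges)) bind_rows(edges) else
                   tibble(feature_a = character(), feature_b = character(), kind = character()),
                 dispersion = dispersion, zero_fraction = zero_fraction,
                 low_zero_fraction = low_zero_fraction,
                 log_mean = log_mean, latent_scale = latent_scale),
            class = "network_truth")
}

#' Simulate an RNA-seq-like count matrix with planted dependency structure
#'
#' Latent Gaussian motifs (first-order chains, equicorrelated triangles,
#' shared latent factors) are mapped to negative-binomial read counts through
#' an exponential link, then zero-inflated per transcript. In a chain
#' X-Y-Z the latent variable Z depends on Y only, so the mutual information
#' between X and Z is bounded by both direct links (data-processing
#' inequality) -- the property the network stage's pruning exploits.
#'
#' @param n Number of samples (at least 30).
#' @param truth A [network_truth()] object.
#' @param seed Integer seed.
#' @return A list with `expression` (counts tibble) and `truth`.
#' @export
simulate_count_matrix <- function(n, truth, seed) {
  stopifnot(inherits(truth, "network_truth"))
  if (n < 30) stop("n must be at least 30", call. = FALSE)
  local_seed(seed, {
    m <- length(truth$features)
    lat <- matrix(stats::rnorm(n * m), n, m, dimnames = list(NULL, truth$features))
    for (mo in truth$motifs) {
      f <- as.character(mo$features)
      s <- mo$strength %||% 0.8
      if (mo$kind == "chain") {
        for (j in seq_along(f)[-1]) {
          lat[, f[j]] <- s * lat[, f[j - 1]] + sqrt(1 - s^2) * lat[, f[j]]
        }
      } else if (mo$kind == "triangle") {
        shared <- stats::rnorm(n)
        for (fj in f) lat[, fj] <- sqrt(s) * shared + sqrt(1 - s) * lat[, fj]
      } else {                                   # latent_factor
        fac <- stats::rnorm(n)
        for (fj in f) lat[, fj] <- s * fac + sqrt(1 - s^2) * lat[, fj]
      }
    }
    mu <- exp(truth$log_mean + truth$latent_scale * lat)
    size <- if (truth$dispersion > 0) 1 / truth$dispersion else Inf
    counts <- matrix(stats::rnbinom(n * m, mu = mu, size = size), n, m,
                     dimnames = dimnames(lat))
    zf <- rep(truth$zero_fraction, m)
    zf[truth$features %in% truth$low_expressed] <- truth$low_zero_fraction
    for (j in seq_len(m)) {
      if (zf[j] > 0) {
        counts[stats::runif(n) < zf[j], j] <- 0L
      }
    }
    ids <- sprintf("G%05d", seq_len(n))
    list(
      expression = tibble(sample_id = ids) |>
        dplyr::bind_cols(as_tibble(counts, .name_repair = "minimal")),
      truth = truth
    )
  })
}
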