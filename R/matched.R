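# Matched case-control resampling with conditional logistic regression.
#
# Cases are matched to eligible controls (age within a window, same sex,
# different family); each resample draws a fresh control set per case and
# fits a stratified conditional logistic model. Stability of each model
# term is summarized by the fraction of resamples with Wald p < alpha and
# by the sample median p-value.

#' Build per-case eligible-control pools
#'
#' A control is eligible for a case when its age differs by at most
#' `age_window` years (boundary inclusive), it has the same sex, and it
#' belongs to a different family. Cases with an empty pool are excluded with
#' a warning.
#'
#' @param ann Annotation tibble with `sample_id`, `outcome`, `age`, `sex`,
#'   `family_id`.
#' @param age_window Matching half-width in years (default 2).
#' @param controls_per_case Controls drawn per case in each resample
#'   (default 1).
#' @return An object of class `match_design`: case ids, named list of
#'   control pools, the matching parameters, and excluded case ids.
#' @export
build_match_pools <- function(ann, age_window = 2, controls_per_case = 1) {
  need <- c("sample_id", "outcome", "age", "sex", "family_id")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  # canonical (sorted) case and pool order so downstream resampling depends
  # only on the design content, never on annotation row order
  cases <- ann |> filter(.data$outcome == 1) |> arrange(.data$sample_id)
  controls <- ann |> filter(.data$outcome == 0)
  if (nrow(cases) == 0) stop("no cases in annotations", call. = FALSE)
  pools <- purrr::map(seq_len(nrow(cases)), function(i) {
    ok <- abs(controls$age - cases$age[i]) <= age_window &
      controls$sex == cases$sex[i] &
      controls$family_id != cases$family_id[i]
    sort(controls$sample_id[ok])
  })
  names(pools) <- cases$sample_id
  empty <- lengths(pools) == 0
  if (all(empty)) stop("every case has an empty control pool", call. = FALSE)
  if (any(empty)) {
    warning(sum(empty), " case(s) excluded for empty control pools: ",
            paste(names(pools)[empty], collapse = ", "), call. = FALSE)
  }
  structure(list(cases = names(pools)[!empty], pools = pools[!empty],
                 excluded = names(pools)[empty],
                 age_window = age_window,
                 controls_per_case = controls_per_case,
                 pool_sizes = lengths(pools[!empty])),
            class = "match_design")
}

#' @export
print.match_design <- function(x, ...) {
  cat("Match design:", length(x$cases), "cases,",
      x$controls_per_case, "control(s)/case, age window +/-",
      x$age_window, "years\n")
  cat("  pool sizes: median", stats::median(x$pool_sizes),
      "range", min(x$pool_sizes), "-", max(x$pool_sizes), "\n")
  if (length(x$excluded)) cat("  excluded (empty pool):", length(x$excluded), "\n")
  invisible(x)
}

# Fit one conditional logistic model; returns p-values and estimates per
# term (p = 1, estimate = NA on failure or dropped terms).
clr_fit_once <- function(frame, term_cols) {
  p <- stats::setNames(rep(1, length(term_cols)), term_cols)
  est <- stats::setNames(rep(NA_real_, length(term_cols)), term_cols)
  f <- stats::as.formula(paste("outcome ~",
                               paste(term_cols, collapse = " + "),
                               "+ strata(stratum)"))
  fit <- tryCatch(
    suppressWarnings(survival::clogit(f, data = frame)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (!is.null(co)) {
      for (tc in intersect(rownames(co), term_cols)) {
        if (is.finite(co[tc, "Pr(>|z|)"])) {
          p[tc] <- co[tc, "Pr(>|z|)"]
          est[tc] <- co[tc, "coef"]
        }
      }
    }
  }
  list(p = p, est = est)
}

#' Resampled conditional logistic regression with stability summaries
#'
#' Repeats, `n_resamples` times: draw `controls_per_case` controls per case
#' from its eligibility pool (uniformly, without replacement within the
#' resample; case processing order is randomized per resample so overlapping
#' pools are shared fairly), form one stratum per case, and maximize the
#' conditional (stratified) logistic likelihood for the requested terms.
#' Wald p-values and estimates are recorded per term and resample. Works
#' unchanged for expression features and for SNP dosage columns
#' (`standardize = FALSE`), including product (epistasis) terms.
#'
#' @param data Tibble with `sample_id` plus numeric columns (expression or
#'   genotype dosages).
#' @param ann Annotation tibble with at least `sample_id` and `outcome`.
#' @param design A [build_match_pools()] object.
#' @param features One feature (single model) or two (pair model).
#' @param interaction With two features, add their product term.
#' @param n_resamples Number of resamples (the full-scale analysis uses
#'   5000; scale down for exploration).
#' @param alpha Per-resample significance level for the Wald test.
#' @param seed Integer seed; identical seeds give identical p-value vectors.
#' @param standardize Z-score feature columns (over analyzed samples) before
#'   forming products; use `FALSE` for dosage coding.
#' @return An object of class `resample_summary`: matrices `p` and
#'   `estimates` (resamples x terms), a `summary` tibble with
#'   `fraction_significant` (exactly `mean(p < alpha)`) and `median_p`, the
#'   model tag and features.
#' @export
clr_bootstrap <- function(data, ann, design, features, interaction = FALSE,
                          n_resamples = 5000, alpha = 0.05, seed = 1,
                          standardize = TRUE) {
  stopifnot(inherits(design, "match_design"),
            length(features) %in% 1:2, all(features %in% names(data)))
  if (interaction && length(features) != 2) {
    stop("interaction requires exactly two features", call. = FALSE)
  }
  ids <- data$sample_id
  x <- as.matrix(data[features])
  rownames(x) <- ids
  used_ids <- unique(c(design$cases, unlist(design$pools, use.names = FALSE)))
  if (!all(used_ids %in% ids)) stop("design references samples absent from data", call. = FALSE)
  if (standardize) {
    x <- scale(x[used_ids, , drop = FALSE])
  } else {
    x <- x[used_ids, , drop = FALSE]
  }
  safe <- paste0("x", seq_along(features))
  term_names <- features
  xx <- x
  colnames(xx) <- safe
  if (interaction) {
    xx <- cbind(xx, x[, 1] * x[, 2])
    colnames(xx)[ncol(xx)] <- "x1_x2"
    term_names <- c(term_names, paste0(features[1], ":", features[2]))
  }
  term_cols <- colnames(xx)
  cases <- design$cases
  cpc <- design$controls_per_case
  outcome_of <- stats::setNames(ann$outcome, ann$sample_id)

  p_mat <- matrix(NA_real_, n_resamples, length(term_cols))
  e_mat <- matrix(NA_real_, n_resamples, length(term_cols))
  local_seed(seed, {
    for (r in seq_len(n_resamples)) {
      order_r <- sample(length(cases))
      used <- character()
      member <- list()
      stratum <- list()
      for (ci in order_r) {
        pool <- setdiff(design$pools[[cases[ci]]], used)
        if (length(pool) < cpc) next
        ctl <- if (length(pool) == 1) pool else sample(pool, cpc)
        used <- c(used, ctl)
        member[[length(member) + 1]] <- c(cases[ci], ctl)
        stratum[[length(stratum) + 1]] <- rep(ci, 1 + cpc)
      }
      samp <- unlist(member)
      st <- unlist(stratum)
      frame <- data.frame(outcome = unname(outcome_of[samp]),
                          stratum = st,
                          xx[samp, , drop = FALSE])
      # drop strata carrying no exposure contrast in any term
      info <- tapply(seq_len(nrow(frame)), frame$stratum, function(ix) {
        any(apply(frame[ix, term_cols, drop = FALSE], 2,
                  function(v) length(unique(v)) > 1))
      })
      keep_st <- as.integer(names(info)[info])
      frame <- frame[frame$stratum %in% keep_st, ]
      if (nrow(frame) == 0) {
        p_mat[r, ] <- 1
        next
      }
      res <- clr_fit_once(frame, term_cols)
      p_mat[r, ] <- res$p[term_cols]
      e_mat[r, ] <- res$est[term_cols]
    }
  })
  colnames(p_mat) <- colnames(e_mat) <- term_names
  summary <- tibble(
    term = term_names,
    fraction_significant = unname(colMeans(p_mat < alpha)),
    median_p = unname(apply(p_mat, 2, stats::median)),
    mean_estimate = unname(colMeans(e_mat, na.rm = TRUE))
  )
  structure(list(p = p_mat, estimates = e_mat, terms = term_names,
                 features = features,
                 model_tag = if (interaction) "pair_interactive"
                             else if (length(features) == 2) "pair_additive"
                             else "single",
                 alpha = alpha, n_resamples = n_resamples,
                 controls_per_case = cpc, summary = summary),
            class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat("CLR resample summary (", x$model_tag, "): ", x$n_resamples,
      " resamples, alpha = ", x$alpha, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Call terms significant from a resample summary
#'
#' Two decision rules: `median_p` calls a term significant when the sample
#' median of its p-values is strictly below 0.05 (equivalently `alpha`);
#' `fraction` when the term was significant in at least half the resamples.
#'
#' @param summary A [clr_bootstrap()] result.
#' @param rule `"median_p"` or `"fraction"`.
#' @param alpha Significance level (defaults to the summary's).
#' @return Tibble with `term`, `statistic`, `significant`.
#' @export
call_significant <- function(summary, rule = c("median_p", "fraction"),
                             alpha = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(summary, "resample_summary"))
  alpha <- alpha %||% summary$alpha
  s <- summary$summary
  if (rule == "median_p") {
    tibble(term = s$term, statistic = s$median_p,
           significant = s$median_p < alpha)
  } else {
    tibble(term = s$term, statistic = s$fraction_significant,
           significant = s$fraction_significant >= 0.5)
  }
}

#' Classify a resample p-value distribution as informative of the outcome
#'
#' A term whose p-values across resamples pile up near zero (a right-skewed
#' histogram of evidence) is informative even when it misses the median-p
#' rule. Operationalized as a one-sided Kolmogorov-Smirnov test of the
#' p-vector against Uniform(0, 1) in the stochastically-smaller direction,
#' combined with the requirement that the sample median lies below 0.5 (so
#' that mass concentrated *above* 0.5, which can also inflate the one-sided
#' KS statistic, is never called informative).
#'
#' @param p_vector Numeric vector of at least 100 p-values in \[0, 1\].
#' @param alpha Level for the KS decision (default 0.05).
#' @return Tibble with `informative` (logical), `statistic` (KS D+),
#'   `p_value`.
#' @export
assess_informativeness <- function(p_vector, alpha = 0.05) {
  if (length(p_vector) < 100) stop("need at least 100 resampled p-values", call. = FALSE)
  ks <- suppressWarnings(
    stats::ks.test(p_vector, "punif", alternative = "greater")
  )
  tibble(informative = unname(ks$p.value < alpha) &&
           stats::median(p_vector) < 0.5,
         statistic = unname(ks$statistic),
         p_value = unname(ks$p.value))
}

#' Drop low-frequency variants before epistasis models
#'
#' Removes dosage columns whose minor-allele count among the given samples
#' is below `min_mac`, so conditional logistic epistasis fits are not run on
#' near-monomorphic variants.
#'
#' @param geno Tibble with `sample_id` plus dosage columns in \{0, 1, 2\}.
#' @param min_mac Minimum minor-allele count (default 10).
#' @return `geno` with failing columns removed (message logged).
#' @export
filter_variants <- function(geno, min_mac = 10) {
  vars <- setdiff(names(geno), "sample_id")
  keep <- vapply(vars, function(v) {
    d <- geno[[v]]
    if (!all(d %in% c(0, 1, 2))) stop("dosages must be 0/1/2: ", v, call. = FALSE)
    ac <- sum(d)
    min(ac, 2 * length(d) - ac) >= min_mac
  }, logical(1))
  if (any(!keep)) {
    message("dropping ", sum(!keep), " variant(s) with minor-allele count < ",
            min_mac, ": ", paste(vars[!keep], collapse = ", "))
  }
  geno[c("sample_id", vars[keep])]
}
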