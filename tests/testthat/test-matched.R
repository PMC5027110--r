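make_matched_ann <- function() {
  tibble::tibble(
    sample_id = c("c1", "k1", "k2", "k3", "k4"),
    outcome = c(1L, 0L, 0L, 0L, 0L),
    age = c(60, 62, 63, 60, 60),
    sex = c("F", "F", "F", "M", "F"),
    family_id = c("f1", "f2", "f2", "f3", "f1")
  )
}

test_that("eligibility rules: inclusive age window, same sex, other family", {
  design <- build_match_pools(make_matched_ann())
  pool <- design$pools[["c1"]]
  expect_true("k1" %in% pool)    # age 62 for case 60: |d| = 2, inclusive
  expect_false("k2" %in% pool)   # age 63: outside the window
  expect_false("k3" %in% pool)   # different sex
  expect_false("k4" %in% pool)   # same family
})

test_that("cases without eligible controls are excluded with a warning", {
  ann <- make_matched_ann()
  ann <- dplyr::bind_rows(ann, tibble::tibble(
    sample_id = "c2", outcome = 1L, age = 99, sex = "F", family_id = "f9"))
  expect_warning(design <- build_match_pools(ann), "excluded")
  expect_equal(design$cases, "c1")
  expect_error(build_match_pools(ann[ann$outcome == 0, ]), "no cases")
})

test_that("clr bootstrap is deterministic and invariant to row order", {
  truth <- cohort_truth(c("A", "B"),
                        covariate_effects = c(age = 0, sex = 0, race = 0))
  f <- simulate_family_cohort(80, 4, 0.12, truth, seed = 42)
  design <- build_match_pools(f$annotations)
  r1 <- clr_bootstrap(f$expression, f$annotations, design, "A",
                      n_resamples = 20, seed = 42)
  r2 <- clr_bootstrap(f$expression, f$annotations, design, "A",
                      n_resamples = 20, seed = 42)
  expect_identical(r1$p, r2$p)

  # shuffling annotation rows must not change the resample summary
  perm <- withr::with_seed(1, sample(nrow(f$annotations)))
  ann_shuf <- f$annotations[perm, ]
  design_shuf <- build_match_pools(ann_shuf)
  r3 <- clr_bootstrap(f$expression, ann_shuf, design_shuf, "A",
                      n_resamples = 20, seed = 42)
  expect_identical(r1$p, r3$p)

  r4 <- clr_bootstrap(f$expression, f$annotations, design, "A",
                      n_resamples = 20, seed = 43)
  expect_false(identical(r1$p, r4$p))
})

test_that("1:1 matching with binary exposure matches the discordant-pair form", {
  # disjoint singleton pools make the resample deterministic, so the CLR
  # estimate must equal log(n10 / n01) from the discordant pairs exactly
  n_pairs <- 60
  ages <- rep(50, 2 * n_pairs)
  ann <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(2 * n_pairs)),
    outcome = rep(c(1L, 0L), n_pairs),
    age = ages + rep(seq_len(n_pairs) * 10, each = 2),  # isolates pairs
    sex = "F",
    family_id = sprintf("f%03d", seq_len(2 * n_pairs))  # all distinct families
  )
  x <- withr::with_seed(42, rbinom(2 * n_pairs, 1, 0.5))
  dat <- tibble::tibble(sample_id = ann$sample_id, E = x)
  design <- build_match_pools(ann)
  rs <- clr_bootstrap(dat, ann, design, "E", n_resamples = 1, seed = 42,
                      standardize = FALSE)
  xc <- x[rep(c(TRUE, FALSE), n_pairs)]
  xk <- x[rep(c(FALSE, TRUE), n_pairs)]
  n10 <- sum(xc == 1 & xk == 0)
  n01 <- sum(xc == 0 & xk == 1)
  expect_equal(unname(rs$estimates[1, "E"]), log(n10 / n01), tolerance = 1e-6)
})

test_that("planted interaction is detected in most resamples", {
  truth <- cohort_truth(
    c("A", "B"),
    beta_pair = tibble::tibble(feature_a = "A", feature_b = "B", beta = 1.2),
    covariate_effects = c(age = 0, sex = 0, race = 0)
  )
  f <- simulate_family_cohort(400, 4, 0.15, truth, seed = 42)
  design <- build_match_pools(f$annotations)
  rs <- clr_bootstrap(f$expression, f$annotations, design, c("A", "B"),
                      interaction = TRUE, n_resamples = 100, seed = 42)
  frac <- rs$summary$fraction_significant[rs$summary$term == "A:B"]
  expect_gt(frac, 0.8)
  # fraction_significant is exactly mean(p < alpha)
  expect_equal(rs$summary$fraction_significant,
               unname(colMeans(rs$p < rs$alpha)))
  expect_equal(rs$summary$median_p, unname(apply(rs$p, 2, median)))
})

test_that("significance calls follow the stated decision rules", {
  rs <- structure(list(
    p = matrix(0.01, 10, 1, dimnames = list(NULL, "A")),
    estimates = matrix(0.5, 10, 1), terms = "A", features = "A",
    model_tag = "single", alpha = 0.05, n_resamples = 10,
    controls_per_case = 1,
    summary = tibble::tibble(term = "A", fraction_significant = 1,
                             median_p = 0.01, mean_estimate = 0.5)
  ), class = "resample_summary")
  expect_true(call_significant(rs, "median_p")$significant)
  expect_true(call_significant(rs, "fraction")$significant)

  # median exactly at the threshold is NOT significant (strict inequality)
  rs$summary$median_p <- 0.05
  expect_false(call_significant(rs, "median_p")$significant)
})

test_that("uniform p-vectors are usually not called significant", {
  p <- withr::with_seed(42, runif(501))
  med <- median(p)
  expect_gt(med, 0.4)   # uniform median concentrates near 0.5
  expect_lt(med, 0.6)
  expect_lt(mean(p < 0.05), 0.1)
})

test_that("informativeness is a right-skew call on the p-value distribution", {
  p_inf <- withr::with_seed(42, rbeta(500, 0.5, 1))     # stochastically small
  expect_true(assess_informativeness(p_inf)$informative)
  p_flat <- withr::with_seed(42, runif(500))
  expect_false(assess_informativeness(p_flat)$informative)
  expect_false(assess_informativeness(rep(0.9, 200))$informative)
  expect_error(assess_informativeness(runif(50)), "at least 100")
})

test_that("low minor-allele-count variants are dropped before epistasis fits", {
  geno <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:50),
    snp_common = rep(c(0, 1, 2, 1, 0), 10),
    snp_rare = c(1, rep(0, 49))
  )
  expect_message(kept <- filter_variants(geno, min_mac = 10), "snp_rare")
  expect_equal(setdiff(names(kept), "sample_id"), "snp_common")
  expect_error(filter_variants(tibble::tibble(sample_id = "a", s = 0.5)),
               "dosages")
})
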