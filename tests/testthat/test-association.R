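test_that("single-gene fit recovers a planted main effect", {
  truth <- cohort_truth("A", beta_main = c(A = 0.8),
                        covariate_effects = c(age = 0, sex = 0, race = 0))
  s <- simulate_cohort(5000, truth, seed = 42)
  fit <- fit_single(s$expression, s$annotations, "A", covariates = character())
  row <- fit$terms[fit$terms$term == "A", ]
  expect_lt(abs(row$estimate - 0.8), 3 * row$std_error)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 5000)
})

test_that("degenerate inputs are rejected or flagged, not silently fitted", {
  s <- tiny_cohort()
  expr <- s$expression
  expr$C <- 1   # constant feature
  expect_error(fit_single(expr, s$annotations, "C"), "zero-variance")

  # perfect separation -> flagged non-converged, no exception
  expr$D <- ifelse(s$annotations$outcome == 1, 5 + seq_len(nrow(expr)) * 1e-4,
                   -5 - seq_len(nrow(expr)) * 1e-4)
  fit <- fit_single(expr, s$annotations, "D", covariates = character())
  expect_false(fit$converged)
})

test_that("pair models have the stated structure and nest properly", {
  s <- tiny_cohort(seed = 42)
  add <- fit_pair(s$expression, s$annotations, "A", "B", interaction = FALSE)
  int <- fit_pair(s$expression, s$annotations, "A", "B", interaction = TRUE)
  expect_equal(sum(add$terms$term %in% c("A", "B", "A:B")), 2)
  expect_true("A:B" %in% int$terms$term)
  # nesting: adding the product term cannot increase deviance
  expect_lte(int$deviance, add$deviance + 1e-8)
})

test_that("interaction Wald p-value is invariant to feature standardization", {
  s <- tiny_cohort(n = 600, seed = 42, beta_pair_ab = 0.5)
  # shift/scale one feature so raw and z-scored fits differ materially
  expr <- s$expression
  expr$A <- 3 * expr$A + 10
  p_std <- fit_pair(expr, s$annotations, "A", "B", standardize = TRUE)
  p_raw <- fit_pair(expr, s$annotations, "A", "B", standardize = FALSE)
  get_p <- function(f) f$terms$p_value[f$terms$term == "A:B"]
  expect_equal(get_p(p_std), get_p(p_raw), tolerance = 1e-6)
})

test_that("path models chain main effects with consecutive products only", {
  truth <- cohort_truth(c("A", "B", "C", "D"))
  s <- simulate_cohort(500, truth, seed = 42)
  fit <- fit_path_model(s$expression, s$annotations, c("A", "B", "C", "D"),
                        covariates = character())
  terms <- fit$terms$term
  expect_true(all(c("A", "B", "C", "D", "A:B", "B:C", "C:D") %in% terms))
  expect_false("A:C" %in% terms)
  expect_false("A:D" %in% terms)

  # 2-node path is the interactive pair model
  f2 <- fit_path_model(s$expression, s$annotations, c("A", "B"),
                       covariates = character())
  fp <- fit_pair(s$expression, s$annotations, "A", "B", interaction = TRUE,
                 covariates = character())
  expect_equal(sort(f2$terms$term), sort(fp$terms$term))
  expect_equal(f2$terms$estimate[f2$terms$term == "A:B"],
               fp$terms$estimate[fp$terms$term == "A:B"], tolerance = 1e-10)

  expect_error(fit_path_model(s$expression, s$annotations, c("A", "A", "B")),
               "duplicate")
})

test_that("planted consecutive path interactions are recovered", {
  truth <- cohort_truth(
    c("A", "B", "C"),
    beta_pair = tibble::tibble(feature_a = c("A", "B"),
                               feature_b = c("B", "C"),
                               beta = c(0.7, 0.7)),
    covariate_effects = c(age = 0, sex = 0, race = 0)
  )
  # average over replicate cohorts so the 3-SE check carries the right
  # Monte-Carlo error for a mean of independent fits
  reps <- purrr::map(1:5, function(i) {
    s <- simulate_cohort(5000, truth, seed = 42 + i)
    fit_path_model(s$expression, s$annotations, c("A", "B", "C"),
                   covariates = character())
  })
  for (key in c("A:B", "B:C")) {
    est <- vapply(reps, function(f) f$terms$estimate[f$terms$term == key],
                  numeric(1))
    se <- vapply(reps, function(f) f$terms$std_error[f$terms$term == key],
                 numeric(1))
    expect_lt(abs(mean(est) - 0.7), 3 * mean(se) / sqrt(length(reps)))
  }
})

test_that("pair screens enumerate C(m,2) pairs and are order-invariant", {
  expect_equal(nrow(enumerate_pairs(sprintf("P%02d", 1:89))), 3916)
  truth <- cohort_truth(c("A", "B", "C", "D"))
  s <- simulate_cohort(300, truth, seed = 42)
  sc1 <- screen_pairs(s$expression, s$annotations, covariates = character())
  expect_equal(sc1$n_pairs, 6)
  sc2 <- screen_pairs(s$expression, s$annotations,
                      features = c("D", "B", "A", "C"),
                      covariates = character())
  expect_identical(sc1$pairs, sc2$pairs)
  expect_identical(sc1$counts, sc2$counts)

  s2 <- tiny_cohort(n = 200)
  expect_equal(screen_pairs(s2$expression, s2$annotations,
                            covariates = character())$n_pairs, 1)
})

test_that("Wald and likelihood-ratio interaction tests agree in rank", {
  truth <- cohort_truth(sprintf("F%02d", 1:21),
                        covariate_effects = c(age = 0, sex = 0, race = 0))
  s <- simulate_cohort(300, truth, seed = 42)
  pairs <- enumerate_pairs(sprintf("F%02d", 1:21))   # 210 null pairs
  ps <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$feature_a[i]; b <- pairs$feature_b[i]
    int <- fit_pair(s$expression, s$annotations, a, b, interaction = TRUE,
                    covariates = character())
    add <- fit_pair(s$expression, s$annotations, a, b, interaction = FALSE,
                    covariates = character())
    lrt <- stats::pchisq(add$deviance - int$deviance, df = 1, lower.tail = FALSE)
    tibble::tibble(wald = int$terms$p_value[int$terms$term == paste0(a, ":", b)],
                   lrt = lrt)
  })
  expect_gt(stats::cor(ps$wald, ps$lrt, method = "spearman"), 0.95)
})

test_that("probe pairs collapse to gene-level interaction edges", {
  # two probes of gene G1 each interacting with gene G2's probe -> one edge
  pairs <- tibble::tibble(
    feature_a = c("p1", "p2", "p3"), feature_b = c("p3", "p3", "p4"),
    gene_a = c("G1", "G1", "G2"), gene_b = c("G2", "G2", "G3"),
    interaction_sig = c(TRUE, TRUE, FALSE)
  )
  g <- build_interaction_graph(pairs, individually_significant = "G1")
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("G1", "G2"))
  expect_equal(igraph::E(g)$n_probe_pairs, 2)
  expect_true(igraph::V(g)$individually_significant[
    igraph::V(g)$name == "G1"])

  empty <- build_interaction_graph(pairs[!pairs$interaction_sig, ][0, ])
  expect_equal(igraph::ecount(empty), 0)
})
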