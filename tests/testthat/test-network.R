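test_that("transcript filter is strict at the non-zero boundary", {
  n <- 100
  expr <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n),
    keep66 = c(rep(1, 66), rep(0, 34)),
    drop65 = c(rep(1, 65), rep(0, 35)),
    full = rnorm(n)
  )
  kept <- filter_transcripts(expr, 0.65)
  expect_true("keep66" %in% names(kept))     # 0.66 > 0.65
  expect_false("drop65" %in% names(kept))    # 0.65 is not > 0.65
  expect_true("full" %in% names(kept))

  all_zero <- tibble::tibble(sample_id = c("a", "b"), t = c(0, 0))
  expect_error(filter_transcripts(all_zero), "all transcripts removed")
})

test_that("equal-frequency bins differ in size by at most one", {
  b9 <- discretize_equal_frequency(matrix(rnorm(9), 9, 1), 3)
  expect_equal(unname(c(table(b9))), c(3L, 3L, 3L))
  b10 <- discretize_equal_frequency(matrix(rnorm(10), 10, 1), 3)
  expect_equal(sort(unname(c(table(b10))), decreasing = TRUE),
               c(4L, 3L, 3L))
  # monotone transforms leave bin labels unchanged
  v <- withr::with_seed(42, rnorm(50))
  expect_identical(discretize_equal_frequency(matrix(v), 5),
                   discretize_equal_frequency(matrix(exp(v)), 5))
  # degenerate features are flagged
  d <- discretize_equal_frequency(cbind(x = rep(1:2, 10), y = rnorm(20)), 4)
  expect_equal(attr(d, "degenerate"), "x")
  expect_error(discretize_equal_frequency(matrix(1:4, 2, 2), 1), "n_bins")
})

test_that("Renyi MI matches direct summation and the Shannon limit", {
  # exact independence table -> 0 for any alpha
  xy <- table_to_bins(matrix(c(0.24, 0.36, 0.16, 0.24), 2, 2), 100L)
  for (a in c(0.3, 0.5, 2)) {
    expect_equal(renyi_mi(xy$x, xy$y, a), 0, tolerance = 1e-12)
  }

  # 2x2 fixture [[0.4, 0.1], [0.1, 0.4]] at alpha = 0.5
  p <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  b <- table_to_bins(p, 10L)
  expect_equal(renyi_mi(b$x, b$y, 0.5), renyi_mi_table_oracle(p, 0.5),
               tolerance = 1e-12)
  expect_equal(renyi_mi(b$x, b$y, 0.5), -2 * log(2 * sqrt(0.1) + 2 * sqrt(0.025)),
               tolerance = 1e-12)   # approx 0.105 nats

  # brute-force oracle agreement on random tables up to 4x4
  withr::with_seed(42, {
    for (rep in 1:20) {
      nr <- sample(2:4, 1); nc <- sample(2:4, 1)
      cnt <- matrix(rpois(nr * nc, 5) + 1, nr, nc)
      p <- cnt / sum(cnt)
      bb <- table_to_bins(p, sum(cnt))
      for (a in c(0.5, 2)) {
        expect_equal(renyi_mi(bb$x, bb$y, a), renyi_mi_table_oracle(p, a),
                     tolerance = 1e-12)
      }
    }
  })

  # alpha -> 1 recovers plug-in Shannon MI
  withr::with_seed(42, {
    for (rep in 1:10) {
      cnt <- matrix(rpois(9, 8) + 1, 3, 3)
      bb <- table_to_bins(cnt / sum(cnt), sum(cnt))
      expect_lt(abs(renyi_mi(bb$x, bb$y, 0.999) -
                      shannon_mi_oracle(bb$x, bb$y)), 1e-3)
    }
  })
})

test_that("Renyi MI is symmetric, label-invariant, and non-negative", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      x <- sample(1:3, 60, replace = TRUE)
      y <- sample(1:4, 60, replace = TRUE)
      a <- runif(1, 0.1, 3); if (abs(a - 1) < 0.01) a <- 1.5
      mi <- renyi_mi(x, y, a)
      expect_gte(mi, 0)
      expect_equal(mi, renyi_mi(y, x, a), tolerance = 1e-12)
      # permute bin labels
      px <- sample(3)[x]
      expect_equal(mi, renyi_mi(px, y, a), tolerance = 1e-12)
    }
  })
  expect_equal(renyi_mi(rep(1, 10), rep(1:2, 5), 0.5), 0)  # degenerate marginal
  expect_error(renyi_mi(1:4, 1:4, 1), "alpha")
})

test_that("population Markov chains obey the data-processing inequality", {
  # analytic chain X -> Y -> Z on binary alphabets, flip prob 0.1
  flip <- 0.1
  pxy <- matrix(c((1 - flip) / 2, flip / 2, flip / 2, (1 - flip) / 2), 2, 2)
  # Z given Y with the same channel; joint XZ by composition
  pz_given_y <- matrix(c(1 - flip, flip, flip, 1 - flip), 2, 2)
  pxz <- pxy %*% pz_given_y
  bxy <- table_to_bins(pxy, 1000L)
  bxz <- table_to_bins(pxz, 1000L)
  for (a in c(0.5, 2)) {
    expect_lt(renyi_mi(bxz$x, bxz$y, a), renyi_mi(bxy$x, bxy$y, a))
  }
})

test_that("DPI pruning removes only strict triangle minima", {
  mi <- matrix(0, 3, 3, dimnames = list(c("i", "j", "l"), c("i", "j", "l")))
  mi["i", "j"] <- mi["j", "i"] <- 0.5
  mi["j", "l"] <- mi["l", "j"] <- 0.4
  mi["i", "l"] <- mi["l", "i"] <- 0.1
  adj <- dpi_prune(mi)
  expect_true(adj["i", "j"] && adj["j", "l"])
  expect_false(adj["i", "l"])

  # three equal edges: no strict minimum, nothing removed
  tie <- matrix(0.3, 3, 3); diag(tie) <- 0
  expect_equal(sum(dpi_prune(tie)) / 2, 3)

  # disjoint edges (no triangle) are untouched
  mi4 <- matrix(0, 4, 4)
  mi4[1, 2] <- mi4[2, 1] <- 0.5
  mi4[3, 4] <- mi4[4, 3] <- 0.1
  expect_equal(sum(dpi_prune(mi4)) / 2, 2)

  # eps shields near-ties from removal
  near <- mi
  near["i", "l"] <- near["l", "i"] <- 0.39
  expect_false(dpi_prune(near, eps = 0)["i", "l"])
  expect_true(dpi_prune(near, eps = 0.05)["i", "l"])
})

test_that("consensus frequencies are exact resample fractions", {
  nt <- network_truth(list(list(kind = "chain", features = c("X", "Y", "Z"),
                                strength = 0.8)))
  s <- simulate_count_matrix(120, nt, seed = 42)
  net1 <- consensus(s$expression, k = 1, n_null = 20, seed = 42)
  expect_true(all(net1$M %in% c(0, 1)))   # k = 1: frequencies are 0/1

  net <- consensus(s$expression, k = 12, n_null = 20, seed = 42)
  expect_true(all(net$M * net$k == round(net$M * net$k)))  # exact counts / k
  expect_equal(net$M, t(net$M))
  expect_equal(unname(diag(net$M)), rep(0, 3))

  # bit-reproducible under the seed, invariant to feature order
  net_b <- consensus(s$expression, k = 12, n_null = 20, seed = 42)
  expect_identical(net$M, net_b$M)
  perm <- s$expression[c("sample_id", "Z", "X", "Y")]
  net_p <- consensus(perm, k = 12, n_null = 20, seed = 42)
  expect_identical(net$M, net_p$M)
})

test_that("thresholding retains by frequency with an inclusive boundary", {
  net <- structure(list(
    M = matrix(c(0, 0.51, 0.499, 0.51, 0, 0, 0.499, 0, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    k = 1000, subsample_size = 80, n_bins = 4, alpha = 0.5, eps = 0,
    n_null = 100, null_quantile = 0.95, features = c("a", "b", "c"),
    n_samples = 100), class = "consensus_network")
  edges <- threshold_edges(net, tau = 0.5)
  expect_true(edges$retained[edges$feature_a == "a" & edges$feature_b == "b"])
  expect_false(edges$retained[edges$feature_a == "a" & edges$feature_b == "c"])
  expect_equal(attr(edges, "frac_observed"), 2 / 3)

  # tau = 0 retains every ever-observed edge
  all_edges <- threshold_edges(net, tau = 0)
  expect_true(all(all_edges$retained))

  # isoform edges within one gene are legal and labeled
  iso <- threshold_edges(net, tau = 0.5, feature_to_gene = tibble::tibble(
    feature_id = c("a", "b", "c"), gene = c("G1", "G1", "G2")))
  ab <- iso[iso$feature_a == "a" & iso$feature_b == "b", ]
  expect_equal(ab$gene_a, ab$gene_b)
})
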