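# Consensus co-expression networks from subsampled Renyi mutual information
# graphs with ARACNE-style data-processing-inequality (DPI) pruning.
#
# Per subsample of individuals: equal-frequency discretization, pairwise
# Renyi MI of order alpha, DPI pruning of the weakest edge of every
# triangle, and a permutation-null support rule for the surviving edges.
# The consensus matrix M(i,j) is the exact fraction of subsamples in which
# edge (i,j) is observed; the stability argument is that a direct dependence
# beats an indirect one in more than half the resamples, so a retention
# threshold of 0.5 separates them.

#' Filter poorly expressed transcripts
#'
#' Keeps a transcript only if it is non-zero in strictly more than
#' `min_nonzero_frac` of samples (default 0.65, i.e. "more than 65%").
#'
#' @param expr Expression tibble (counts or intensities).
#' @param min_nonzero_frac Strict lower bound on the non-zero fraction.
#' @return The filtered expression tibble.
#' @export
filter_transcripts <- function(expr, min_nonzero_frac = 0.65) {
  check_expression(expr)
  m <- expr_to_matrix(expr)
  frac <- colMeans(m != 0)
  keep <- frac > min_nonzero_frac
  if (!any(keep)) stop("all transcripts removed by the non-zero filter", call. = FALSE)
  expr[c("sample_id", colnames(m)[keep])]
}

#' Equal-frequency discretization
#'
#' Bins each feature into `n_bins` equal-frequency (quantile) bins; per
#' feature, bin counts differ by at most one, with ties broken by stable
#' sample order. Bin labels are invariant to monotone transforms of a
#' feature. Features with fewer than `n_bins` distinct values are still
#' binned but flagged in the `"degenerate"` attribute.
#'
#' @param expr Expression tibble or numeric matrix (samples x features).
#' @param n_bins Number of bins (>= 2, and at most the number of samples).
#' @return Integer matrix of bin labels in `1..n_bins` with a `"n_bins"`
#'   attribute.
#' @export
discretize_equal_frequency <- function(expr, n_bins) {
  m <- if (is.data.frame(expr)) expr_to_matrix(expr) else as.matrix(expr)
  n <- nrow(m)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (n < n_bins) stop("need at least n_bins samples", call. = FALSE)
  bins <- apply(m, 2, function(v) {
    r <- rank(v, ties.method = "first")
    as.integer(((r - 1) * n_bins) %/% n + 1L)
  })
  degen <- apply(m, 2, function(v) length(unique(v)) < n_bins)
  cn <- colnames(m) %||% as.character(seq_len(ncol(m)))
  structure(bins, n_bins = n_bins, degenerate = cn[degen])
}

#' Renyi mutual information of order alpha between two discretized features
#'
#' Plug-in estimate of the Renyi divergence of order `alpha` between the
#' empirical joint distribution of the two bin vectors and the product of
#' their marginals:
#' \deqn{D_\alpha = \frac{1}{\alpha - 1}\log \sum_{x,y}
#'   p(x,y)^\alpha \, (p(x)p(y))^{1-\alpha}}
#' in nats. Empty joint cells contribute zero for `alpha < 1`. The measure
#' is symmetric, non-negative, invariant to bin relabeling, and recovers
#' plug-in Shannon mutual information as `alpha -> 1`. A degenerate marginal
#' (a single occupied bin) gives 0.
#'
#' @param x_bins,y_bins Equal-length integer bin vectors.
#' @param alpha Renyi order, positive and not equal to 1 (default 0.5, the
#'   symmetric order).
#' @return Non-negative scalar, in nats.
#' @export
renyi_mi <- function(x_bins, y_bins, alpha = 0.5) {
  if (alpha <= 0 || alpha == 1) stop("alpha must be > 0 and != 1", call. = FALSE)
  if (length(x_bins) != length(y_bins)) stop("bin vectors must have equal length", call. = FALSE)
  x <- as.integer(factor(x_bins))
  y <- as.integer(factor(y_bins))
  nx <- max(x); ny <- max(y)
  if (nx < 2 || ny < 2) return(0)
  n <- length(x)
  joint <- tabulate((x - 1L) * ny + y, nbins = nx * ny) / n
  px <- rowSums(matrix(joint, nx, ny, byrow = TRUE))
  py <- colSums(matrix(joint, nx, ny, byrow = TRUE))
  prod_marg <- as.vector(t(outer(px, py)))   # same (x-major) cell order as joint
  nz <- joint > 0
  s <- sum(joint[nz]^alpha * prod_marg[nz]^(1 - alpha))
  max(0, log(s) / (alpha - 1))
}

# All pairwise Renyi MI values; symmetric matrix with zero diagonal.
renyi_mi_matrix <- function(bins, alpha = 0.5) {
  m <- ncol(bins)
  out <- matrix(0, m, m, dimnames = list(colnames(bins), colnames(bins)))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- renyi_mi(bins[, i], bins[, j], alpha)
    }
  }
  out
}

#' Prune indirect edges with the data-processing inequality
#'
#' ARACNE-style rule: for every triangle (i, j, l) whose three edges are all
#' present, the edge with the strictly smallest mutual information is
#' removed if it is smaller than both others by more than `eps`. All
#' triangles are evaluated against the original MI values, so the result
#' does not depend on traversal order. Ties (no strict minimum) remove
#' nothing.
#'
#' @param mi_matrix Symmetric non-negative MI matrix.
#' @param eps Tolerance subtracted from the competing edges (default 0,
#'   strict).
#' @param present Optional logical adjacency restricting which edges exist
#'   (default: every positive-MI edge).
#' @return Logical adjacency matrix of surviving edges.
#' @export
dpi_prune <- function(mi_matrix, eps = 0, present = NULL) {
  mi <- as.matrix(mi_matrix)
  if (!isTRUE(all.equal(mi, t(mi), tolerance = 1e-12))) {
    stop("mi_matrix must be symmetric", call. = FALSE)
  }
  m <- ncol(mi)
  adj <- if (is.null(present)) mi > 0 else as.matrix(present)
  diag(adj) <- FALSE
  if (m < 3) return(adj)
  drop <- matrix(FALSE, m, m)
  trip <- utils::combn(m, 3)
  for (t in seq_len(ncol(trip))) {
    i <- trip[1, t]; j <- trip[2, t]; l <- trip[3, t]
    if (!(adj[i, j] && adj[j, l] && adj[i, l])) next
    w <- c(mi[i, j], mi[j, l], mi[i, l])
    mn <- which.min(w)
    if (sum(w == w[mn]) > 1) next                 # no strict minimum
    if (w[mn] < min(w[-mn]) - eps) {
      ii <- rbind(c(i, j), c(j, l), c(i, l))[mn, ]
      drop[ii[1], ii[2]] <- drop[ii[2], ii[1]] <- TRUE
    }
  }
  out <- adj & !drop
  dimnames(out) <- dimnames(mi)
  out
}

# Per-pair permutation-null MI threshold: for each pair, the
# `null_quantile` quantile of MI between feature i and n_null row
# permutations of feature j.
null_thresholds <- function(bins, alpha, n_null, null_quantile) {
  m <- ncol(bins)
  n <- nrow(bins)
  perms <- replicate(n_null, sample.int(n))
  thr <- matrix(0, m, m, dimnames = list(colnames(bins), colnames(bins)))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      nulls <- vapply(seq_len(n_null), function(b) {
        renyi_mi(bins[, i], bins[perms[, b], j], alpha)
      }, numeric(1))
      thr[i, j] <- thr[j, i] <- stats::quantile(nulls, null_quantile, names = FALSE)
    }
  }
  thr
}

#' Consensus co-expression network over individual subsamples
#'
#' For each of `k` subsamples of individuals (drawn without replacement),
#' discretizes the expression submatrix into equal-frequency bins, computes
#' all pairwise Renyi MI values, prunes triangles with the data-processing
#' inequality, and calls an edge "observed" when it survives pruning *and*
#' its MI exceeds a per-pair permutation-null quantile (the support rule
#' that makes "co-expressed" well-defined; without it every pruned graph is
#' near-complete). The consensus matrix entry M(i,j) is exactly the number
#' of subsamples whose graph contains edge (i,j), divided by `k`.
#'
#' @param expr Expression tibble (run [filter_transcripts()] first for
#'   count data).
#' @param alpha Renyi order (default 0.5).
#' @param n_bins Bins per feature; default `ceiling(I^(1/3))` for subsample
#'   size I.
#' @param k Number of resamples. Default mirrors the two study regimes:
#'   50000 for small networks (at most 200 features), 300 for large ones;
#'   pass an explicit `k` for desk-scale runs.
#' @param subsample_frac Fraction of samples per subsample (default 0.8,
#'   without replacement).
#' @param eps DPI tolerance (default 0, strict).
#' @param n_null Permutations per pair per resample for the support null
#'   (default 100).
#' @param null_quantile Null quantile an observed edge must exceed
#'   (default 0.95).
#' @param seed Integer seed; consensus frequencies are bit-reproducible
#'   under a fixed seed and invariant to feature order.
#' @return An object of class `consensus_network`: the frequency matrix
#'   `M`, `k`, `subsample_size`, and the tuning parameters.
#' @export
consensus <- function(expr, alpha = 0.5, n_bins = NULL, k = NULL,
                      subsample_frac = 0.8, eps = 0,
                      n_null = 100, null_quantile = 0.95, seed = 1) {
  check_expression(expr)
  mat <- expr_to_matrix(expr)
  feats <- sort(colnames(mat))
  mat <- mat[, feats, drop = FALSE]
  n <- nrow(mat)
  m <- ncol(mat)
  if (m < 2) stop("need at least two features", call. = FALSE)
  k <- k %||% if (m <= 200) 50000L else 300L
  sub_n <- ceiling(subsample_frac * n)
  if (sub_n >= n) sub_n <- n - 1L
  if (sub_n < 10) stop("subsample too small; need more samples", call. = FALSE)
  n_bins <- n_bins %||% ceiling(sub_n^(1 / 3))
  freq <- matrix(0, m, m, dimnames = list(feats, feats))
  local_seed(seed, {
    for (r in seq_len(k)) {
      idx <- sample.int(n, sub_n)
      bins <- discretize_equal_frequency(mat[idx, , drop = FALSE], n_bins)
      mi <- renyi_mi_matrix(bins, alpha)
      surv <- dpi_prune(mi, eps = eps)
      thr <- null_thresholds(bins, alpha, n_null, null_quantile)
      obs <- surv & (mi > thr)
      freq <- freq + obs
    }
  })
  structure(list(M = freq / k, k = k, subsample_size = sub_n,
                 n_bins = n_bins, alpha = alpha, eps = eps,
                 n_null = n_null, null_quantile = null_quantile,
                 features = feats, n_samples = n),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  up <- x$M[upper.tri(x$M)]
  cat("Consensus network:", length(x$features), "features,", x$k,
      "resamples of", x$subsample_size, "individuals\n")
  cat("  alpha =", x$alpha, " bins =", x$n_bins, "\n")
  cat("  pairs ever observed:", sum(up > 0), "/", length(up),
      " max frequency:", if (length(up)) max(up) else NA, "\n")
  invisible(x)
}

#' Threshold a consensus network into a retained edge set
#'
#' Retains edge (i, j) when its consensus frequency `M(i, j) >= tau`
#' (default 0.5: observed in at least half of the resamples). Also reports
#' the fraction of all pairs observed at least once and the fraction
#' retained.
#'
#' @param net A [consensus()] result.
#' @param tau Retention threshold on the consensus frequency.
#' @param feature_to_gene Optional (`feature_id`, `gene`) map; features of
#'   one gene may form edges (isoform co-expression) and are reported as
#'   such.
#' @return Edge tibble (`feature_a`, `feature_b`, `gene_a`, `gene_b`,
#'   `frequency`, `retained`) covering every ever-observed pair, with
#'   attributes `tau`, `frac_observed`, `frac_retained`.
#' @export
threshold_edges <- function(net, tau = 0.5, feature_to_gene = NULL) {
  stopifnot(inherits(net, "consensus_network"))
  M <- net$M
  ut <- which(upper.tri(M), arr.ind = TRUE)
  edges <- tibble(
    feature_a = rownames(M)[ut[, 1]],
    feature_b = colnames(M)[ut[, 2]],
    frequency = M[ut]
  ) |>
    mutate(gene_a = genes_of(.data$feature_a, feature_to_gene),
           gene_b = genes_of(.data$feature_b, feature_to_gene),
           retained = .data$frequency >= tau) |>
    filter(.data$frequency > 0) |>
    select("feature_a", "feature_b", "gene_a", "gene_b", "frequency", "retained") |>
    arrange(.data$feature_a, .data$feature_b)
  n_pairs <- nrow(ut)
  structure(edges,
            tau = tau,
            frac_observed = nrow(edges) / n_pairs,
            frac_retained = sum(edges$retained) / n_pairs)
}

#' Retained graph of a thresholded consensus network
#'
#' @param edges A [threshold_edges()] tibble (or any edge tibble with
#'   `feature_a`, `feature_b`, `frequency`, `retained`).
#' @param all_features Optional vertex universe to include isolated nodes.
#' @return An undirected `igraph` with edge attribute `frequency`.
#' @export
retained_graph <- function(edges, all_features = NULL) {
  kept <- edges |> filter(.data$retained)
  verts <- sort(unique(c(all_features, kept$feature_a, kept$feature_b)))
  igraph::graph_from_data_frame(
    kept |> select("feature_a", "feature_b", "frequency"),
    directed = FALSE, vertices = tibble(name = verts)
  )
}
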