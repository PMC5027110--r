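# Independent oracles and small in-code fixtures used across the suite.

# Plug-in Shannon mutual information (nats) from two bin vectors, written
# directly from the KL definition -- independent of the package's Renyi path.
shannon_mi_oracle <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(as.numeric(s))
}

# Renyi divergence between an explicit joint probability table and the
# product of its marginals, by naive double loop over cells.
renyi_mi_table_oracle <- function(p, alpha) {
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j]^alpha * (px[i] * py[j])^(1 - alpha)
    }
  }
  log(s) / (alpha - 1)
}

# Expand a joint probability table (with rational entries) into bin vectors
# whose empirical distribution equals the table exactly.
table_to_bins <- function(p, denom = 1000L) {
  counts <- round(p * denom)
  stopifnot(sum(counts) == denom)
  x <- integer(); y <- integer()
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      x <- c(x, rep.int(i, counts[i, j]))
      y <- c(y, rep.int(j, counts[i, j]))
    }
  }
  list(x = x, y = y)
}

# All simple paths between two nodes of an undirected graph given as an
# edge list (two-column character matrix), by exhaustive recursion.
all_simple_paths_oracle <- function(edges, source, target) {
  nbr <- list()
  add <- function(a, b) nbr[[a]] <<- sort(unique(c(nbr[[a]], b)))
  for (r in seq_len(nrow(edges))) {
    add(edges[r, 1], edges[r, 2]); add(edges[r, 2], edges[r, 1])
  }
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == target) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nb in nbr[[last]] %||% character()) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  if (!is.null(nbr[[source]])) walk(source)
  if (!length(out)) return(list())
  len <- vapply(out, length, integer(1))
  key <- vapply(out, paste, character(1), collapse = "\x01")
  out[order(len, key)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random undirected simple graph on node names, as an edge-list matrix.
random_graph_edges <- function(n_nodes, p_edge = 0.45) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs[keep, , drop = FALSE]
}

# Small two-feature cohort used by several fixtures.
tiny_cohort <- function(n = 400, seed = 42, beta_pair_ab = 0,
                        beta_main = NULL) {
  truth <- cohort_truth(
    c("A", "B"),
    beta_main = beta_main,
    beta_pair = if (beta_pair_ab != 0) {
      tibble::tibble(feature_a = "A", feature_b = "B", beta = beta_pair_ab)
    } else NULL
  )
  simulate_cohort(n, truth, seed = seed)
}
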