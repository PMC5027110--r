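# Relay-path discovery: k shortest loopless paths between candidate
# transcripts in a retained co-expression graph, and path-chained logistic
# models assessing the disease relevance of each path.

as_path_graph <- function(graph) {
  if (igraph::is_igraph(graph)) return(graph)
  if (is.data.frame(graph)) return(retained_graph(graph))
  stop("graph must be an igraph or an edge tibble", call. = FALSE)
}

# Deterministic k-shortest-loopless-paths: best-first search over simple
# paths ordered by (cost, lexicographic node sequence). Exact for the small,
# sparse retained graphs this stage runs on; `max_pop` bounds the search.
#' Find the k shortest loopless paths between two features
#'
#' Enumerates up to `k` simple paths from `source` to `target`, ordered by
#' path cost and then lexicographically by node sequence (so results are
#' reproducible under any internal node ordering). Cost is hop count by
#' default, or `1 - frequency` summed along the path when
#' `weight = "one_minus_frequency"` and the graph carries a `frequency`
#' edge attribute. Disconnected endpoints give an empty result, not an
#' error.
#'
#' @param graph An undirected `igraph` (e.g. [retained_graph()]) or a
#'   [threshold_edges()] tibble.
#' @param source,target Distinct node names present in the graph.
#' @param k Maximum number of paths (default 5).
#' @param weight `"hops"` or `"one_minus_frequency"`.
#' @param max_pop Safety cap on search expansions.
#' @return A tibble with `rank`, `path` (list of node-id vectors),
#'   `path_str`, `n_hops`, `cost`, and `min_edge_frequency` when edge
#'   frequencies are available.
#' @export
k_shortest_paths <- function(graph, source, target, k = 5,
                             weight = c("hops", "one_minus_frequency"),
                             max_pop = 1e6) {
  weight <- match.arg(weight)
  g <- as_path_graph(graph)
  nodes <- igraph::V(g)$name
  if (source == target) stop("source and target must differ", call. = FALSE)
  if (!(source %in% nodes) || !(target %in% nodes)) {
    stop("source/target not in graph", call. = FALSE)
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  names(adj) <- nodes
  nbrs <- lapply(adj, function(vs) sort(nodes[as.integer(vs)]))
  edge_cost <- function(a, b) {
    if (weight == "hops") return(1)
    eid <- igraph::get_edge_ids(g, c(a, b))
    f <- igraph::edge_attr(g, "frequency", eid)
    if (is.null(f) || is.na(f)) 1 else 1 - f
  }
  # frontier of partial simple paths, keyed for (cost, lex) ordering
  frontier <- list(list(path = source, cost = 0))
  found <- list()
  pops <- 0L
  while (length(frontier) && length(found) < k && pops < max_pop) {
    costs <- vapply(frontier, `[[`, numeric(1), "cost")
    keys <- vapply(frontier, function(p) paste(p$path, collapse = "\x01"), character(1))
    best <- order(costs, keys)[1]
    cur <- frontier[[best]]
    frontier[[best]] <- NULL
    pops <- pops + 1L
    last <- cur$path[length(cur$path)]
    if (last == target) {
      found[[length(found) + 1]] <- cur
      next
    }
    for (nb in nbrs[[last]]) {
      if (nb %in% cur$path) next
      frontier[[length(frontier) + 1]] <-
        list(path = c(cur$path, nb), cost = cur$cost + edge_cost(last, nb))
    }
  }
  if (!length(found)) {
    return(tibble(rank = integer(), path = list(), path_str = character(),
                  n_hops = integer(), cost = numeric(),
                  min_edge_frequency = numeric()))
  }
  freq_of <- function(p) {
    f <- vapply(seq_len(length(p) - 1), function(i) {
      eid <- igraph::get_edge_ids(g, c(p[i], p[i + 1]))
      fa <- igraph::edge_attr(g, "frequency", eid)
      if (is.null(fa)) NA_real_ else fa
    }, numeric(1))
    if (all(is.na(f))) NA_real_ else min(f, na.rm = TRUE)
  }
  tibble(
    rank = seq_along(found),
    path = purrr::map(found, "path"),
    path_str = vapply(found, function(p) paste(p$path, collapse = "|"), character(1)),
    n_hops = vapply(found, function(p) length(p$path) - 1L, integer(1)),
    cost = vapply(found, `[[`, numeric(1), "cost"),
    min_edge_frequency = vapply(found, function(p) freq_of(p$path), numeric(1))
  )
}

#' Fit path-chained disease models along relay paths
#'
#' Applies [fit_path_model()] to each path and flags, at level `alpha`,
#' every node (main effect) and every consecutive-pair product term.
#'
#' @param paths A [k_shortest_paths()] tibble.
#' @param expr,ann Cohort expression and annotations (all path features must
#'   be columns of `expr`).
#' @param alpha Significance level for the flags.
#' @param ... Passed to [fit_path_model()].
#' @return `paths` with added list-columns `fit`, `node_significant`,
#'   `edge_significant`, and logical `any_significant`.
#' @export
evaluate_paths <- function(paths, expr, ann, alpha = 0.05, ...) {
  stopifnot(is.data.frame(paths), "path" %in% names(paths))
  fits <- purrr::map(paths$path, function(p) fit_path_model(expr, ann, p, ...))
  node_sig <- purrr::map2(fits, paths$path, function(f, p) {
    ps <- stats::setNames(f$terms$p_value, f$terms$term)
    stats::setNames(unname(ps[p]) < alpha, p)
  })
  edge_sig <- purrr::map2(fits, paths$path, function(f, p) {
    keys <- paste0(p[-length(p)], ":", p[-1])
    ps <- stats::setNames(f$terms$p_value, f$terms$term)
    stats::setNames(unname(ps[keys]) < alpha, keys)
  })
  paths |>
    mutate(fit = fits,
           node_significant = node_sig,
           edge_significant = edge_sig,
           any_significant = purrr::map2_lgl(node_sig, edge_sig,
                                            ~ any(.x) || any(.y)))
}

#' Overlap between interacting pairs and retained co-expression edges
#'
#' Counts how many gene pairs with a significant non-linear interaction are
#' also retained co-expression edges. Pairs with a gene absent from the
#' co-expression analysis (e.g. removed by the expression filter) are
#' reported as untested and excluded from the denominator.
#'
#' @param interaction_pairs Tibble with `gene_a`, `gene_b` (e.g. significant
#'   rows of a [screen_pairs()] result).
#' @param coexpression_edges A [threshold_edges()] tibble at gene level.
#' @param tested_genes Genes that entered the co-expression analysis;
#'   defaults to every gene appearing in `coexpression_edges`.
#' @return One-row tibble: `n_pairs`, `n_tested`, `n_untested`, `n_overlap`,
#'   `overlap_fraction`, `overlap_percent`.
#' @export
candidate_overlap_report <- function(interaction_pairs, coexpression_edges,
                                     tested_genes = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(interaction_pairs)))
  tested_genes <- tested_genes %||%
    unique(c(coexpression_edges$gene_a, coexpression_edges$gene_b))
  ip <- unique(pair_key(interaction_pairs$gene_a, interaction_pairs$gene_b))
  kept <- coexpression_edges |> filter(.data$retained)
  ce <- unique(pair_key(kept$gene_a, kept$gene_b))
  a <- sub("\\|.*", "", ip); b <- sub(".*\\|", "", ip)
  testable <- a %in% tested_genes & b %in% tested_genes
  n_tested <- sum(testable)
  n_overlap <- sum(ip[testable] %in% ce)
  tibble(n_pairs = length(ip), n_tested = n_tested,
         n_untested = sum(!testable), n_overlap = n_overlap,
         overlap_fraction = if (n_tested) n_overlap / n_tested else NA_real_,
         overlap_percent = if (n_tested) 100 * n_overlap / n_tested else NA_real_)
}
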