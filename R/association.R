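# Logistic models on an unmatched cohort: single-gene screens, additive and
# interactive pair models, and path-chained models (main effect for every
# node, product term for each consecutive pair). A pair of transcripts is
# called "interacting non-linearly" when the Wald p-value of its product
# term falls below alpha, regardless of the main effects.

default_covariates <- function(ann) {
  intersect(c("age", "sex", "race"), names(ann))
}

# Assemble the analysis frame: z-scored (optionally) feature columns under
# safe names x1..xk, product columns for the requested index pairs, factor
# covariates, and the outcome. Rows with missing covariates are dropped with
# a message.
build_frame <- function(expr, ann, features, prod_pairs, covariates, standardize) {
  check_expression(expr)
  dat <- inner_join(expr[c("sample_id", features)], ann, by = "sample_id")
  keep <- stats::complete.cases(dat[c("outcome", covariates)])
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing outcome/covariates")
    dat <- dat[keep, ]
  }
  if (length(unique(dat$outcome)) < 2) {
    stop("outcome must include both cases and controls", call. = FALSE)
  }
  x <- as.matrix(dat[features])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(features[sds == 0], collapse = ", "), call. = FALSE)
  }
  feature_summary <- tibble(
    feature = features, sd = sds, mean = colMeans(x),
    q01 = apply(x, 2, stats::quantile, 0.01),
    q99 = apply(x, 2, stats::quantile, 0.99)
  )
  if (standardize) x <- scale(x)
  safe <- paste0("x", seq_along(features))
  frame <- as.data.frame(x)
  names(frame) <- safe
  term_map <- stats::setNames(features, safe)
  for (p in seq_len(nrow(prod_pairs))) {
    i <- prod_pairs[p, 1]; j <- prod_pairs[p, 2]
    nm <- paste0("x", i, "_x", j)
    frame[[nm]] <- x[, i] * x[, j]
    term_map[nm] <- paste0(features[i], ":", features[j])
  }
  for (cv in covariates) {
    frame[[cv]] <- if (is.character(dat[[cv]])) factor(dat[[cv]]) else dat[[cv]]
  }
  frame$..y.. <- dat$outcome
  list(frame = frame, term_map = term_map, feature_summary = feature_summary,
       n_used = nrow(frame), n_dropped = sum(!keep))
}

fit_logistic <- function(parts, model_tag, features, standardized = TRUE) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(..y.. ~ ., data = parts$frame, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- summary(fit)$coefficients
  term <- rownames(co)
  mapped <- ifelse(term %in% names(parts$term_map), parts$term_map[term], term)
  structure(list(
    model_tag = model_tag,
    features = features,
    terms = tibble(term = unname(mapped),
                   estimate = unname(co[, "Estimate"]),
                   std_error = unname(co[, "Std. Error"]),
                   p_value = unname(co[, "Pr(>|z|)"])),
    converged = fit$converged && !sep,
    n_used = parts$n_used,
    n_dropped = parts$n_dropped,
    feature_summary = parts$feature_summary,
    deviance = fit$deviance,
    standardized = standardized,
    glm = fit,
    term_map = parts$term_map
  ), class = "coexpair_fit")
}

#' Single-gene logistic screen
#'
#' Fits a maximum-likelihood logistic regression of the binary outcome on
#' one expression feature plus covariates, reporting the Wald test per term.
#' Perfect separation is flagged (`converged = FALSE`), not raised.
#'
#' @param expr Expression tibble (`sample_id` + numeric feature columns).
#' @param ann Annotation tibble with `sample_id`, `outcome`, covariates.
#' @param feature Feature (column) to test.
#' @param covariates Covariate column names; defaults to whichever of
#'   `age`, `sex`, `race` are present in `ann`.
#' @param standardize Z-score the feature before fitting (default `TRUE`),
#'   so estimates are per SD of expression.
#' @return A `coexpair_fit` object; see [tidy.coexpair_fit()].
#' @export
fit_single <- function(expr, ann, feature, covariates = default_covariates(ann),
                       standardize = TRUE) {
  stopifnot(feature %in% names(expr))
  parts <- build_frame(expr, ann, feature, matrix(numeric(), 0, 2),
                       covariates, standardize)
  fit_logistic(parts, "single", feature, standardize)
}

#' Gene-pair logistic model, additive or interactive
#'
#' Fits `outcome ~ A + B (+ A:B) + covariates`. With `interaction = TRUE`
#' the product of the two (optionally z-scored) expression vectors enters as
#' an extra term; its Wald p-value defines non-linear interaction.
#'
#' @inheritParams fit_single
#' @param feature_a,feature_b The two features.
#' @param interaction Include the product term?
#' @return A `coexpair_fit` with `model_tag` `"pair_additive"` or
#'   `"pair_interactive"`.
#' @export
fit_pair <- function(expr, ann, feature_a, feature_b, interaction = TRUE,
                     covariates = default_covariates(ann), standardize = TRUE) {
  stopifnot(feature_a %in% names(expr), feature_b %in% names(expr),
            feature_a != feature_b)
  prods <- if (interaction) matrix(c(1, 2), 1, 2) else matrix(numeric(), 0, 2)
  parts <- build_frame(expr, ann, c(feature_a, feature_b), prods,
                       covariates, standardize)
  fit_logistic(parts, if (interaction) "pair_interactive" else "pair_additive",
               c(feature_a, feature_b), standardize)
}

#' Path-chained logistic model
#'
#' For an ordered path of transcripts, fits a logistic model with a main
#' effect for every node and a product term for every *consecutive* pair
#' only: `outcome ~ R1 + ... + Rk + R1:R2 + ... + R(k-1):Rk + covariates`.
#' A 2-node path is identical to [fit_pair()] with an interaction.
#'
#' @inheritParams fit_single
#' @param path Ordered character vector of at least two distinct features.
#' @return A `coexpair_fit` with `model_tag = "path"`.
#' @export
fit_path_model <- function(expr, ann, path, covariates = default_covariates(ann),
                           standardize = TRUE) {
  path <- as.character(path)
  if (length(path) < 2) stop("path must have at least 2 features", call. = FALSE)
  if (anyDuplicated(path)) stop("duplicate feature in path", call. = FALSE)
  stopifnot(all(path %in% names(expr)))
  prods <- cbind(seq_len(length(path) - 1), seq_len(length(path) - 1) + 1)
  parts <- build_frame(expr, ann, path, prods, covariates, standardize)
  fit_logistic(parts, "path", path, standardize)
}

term_status <- function(p_a, p_b, alpha) {
  n_sig <- (p_a < alpha) + (p_b < alpha)
  c("none_sig", "one_sig", "both_sig")[n_sig + 1]
}

#' Screen all feature pairs with additive and interactive models
#'
#' Enumerates every unordered pair of the given features, fits both the
#' additive and interactive logistic models, and classifies each pair: how
#' many expression main effects reach `alpha` under each model, and whether
#' the product term is significant (the non-linear interaction call, made
#' regardless of main-effect significance). A Benjamini-Hochberg adjusted
#' interaction p-value is reported for reference but not used in the calls.
#'
#' @inheritParams fit_single
#' @param features Features to screen; default all expression columns.
#' @param alpha Nominal significance level (default 0.05).
#' @param feature_to_gene Optional tibble (`feature_id`, `gene`) mapping
#'   probes/transcripts to gene symbols for the summary counts.
#' @return An object of class `pair_screen`: list with `pairs` (one row per
#'   pair), `counts` (per-model number of pairs with >= 1 significant
#'   expression term and number of distinct genes involved), and `alpha`.
#' @export
screen_pairs <- function(expr, ann, features = NULL, alpha = 0.05,
                         feature_to_gene = NULL,
                         covariates = default_covariates(ann),
                         standardize = TRUE) {
  features <- features %||% setdiff(names(expr), "sample_id")
  if (length(features) < 2) stop("need at least 2 features", call. = FALSE)
  pairs <- enumerate_pairs(features)
  one <- function(a, b) {
    add <- fit_pair(expr, ann, a, b, interaction = FALSE,
                    covariates = covariates, standardize = standardize)
    int <- fit_pair(expr, ann, a, b, interaction = TRUE,
                    covariates = covariates, standardize = standardize)
    p_add <- stats::setNames(add$terms$p_value, add$terms$term)
    p_int <- stats::setNames(int$terms$p_value, int$terms$term)
    key <- paste0(a, ":", b)
    tibble(
      feature_a = a, feature_b = b,
      additive_status = term_status(p_add[[a]], p_add[[b]], alpha),
      interactive_status = term_status(p_int[[a]], p_int[[b]], alpha),
      interaction_estimate = int$terms$estimate[int$terms$term == key],
      interaction_p = p_int[[key]],
      interaction_sig = p_int[[key]] < alpha,
      converged_additive = add$converged,
      converged_interactive = int$converged
    )
  }
  tab <- purrr::map2(pairs$feature_a, pairs$feature_b, one) |> bind_rows()
  tab$interaction_p_adj <- stats::p.adjust(tab$interaction_p, method = "BH")
  tab$gene_a <- genes_of(tab$feature_a, feature_to_gene)
  tab$gene_b <- genes_of(tab$feature_b, feature_to_gene)
  counts <- tibble(
    model = c("additive", "interactive"),
    n_significant_pairs = c(sum(tab$additive_status != "none_sig"),
                            sum(tab$interactive_status != "none_sig")),
    n_genes = c(
      dplyr::n_distinct(c(tab$gene_a[tab$additive_status != "none_sig"],
                          tab$gene_b[tab$additive_status != "none_sig"])),
      dplyr::n_distinct(c(tab$gene_a[tab$interactive_status != "none_sig"],
                          tab$gene_b[tab$interactive_status != "none_sig"]))
    )
  )
  structure(list(pairs = tab, counts = counts, alpha = alpha,
                 n_pairs = nrow(tab)),
            class = "pair_screen")
}

#' @export
print.pair_screen <- function(x, ...) {
  cat("Pair screen:", x$n_pairs, "pairs at alpha =", x$alpha, "\n")
  cat("  interacting (significant product term):", sum(x$pairs$interaction_sig), "\n")
  print(x$counts)
  invisible(x)
}

#' Gene-level graph of non-linear interactions
#'
#' Collapses significant probe-pair interactions to a simple undirected
#' gene-level graph: an edge joins two genes when *any* probe pair between
#' them has a significant product term. Probe pairs within one gene are
#' dropped (self-loops).
#'
#' @param screen A `pair_screen` or its `pairs` tibble.
#' @param individually_significant Optional character vector of genes with a
#'   significant single-gene screen, stored as a node attribute.
#' @return An `igraph` undirected graph; nodes are genes, edge attribute
#'   `n_probe_pairs` counts the collapsing probe pairs.
#' @export
build_interaction_graph <- function(screen, individually_significant = character()) {
  tab <- if (inherits(screen, "pair_screen")) screen$pairs else screen
  sig <- tab |> filter(.data$interaction_sig)
  edges <- sig |>
    mutate(g1 = pmin(.data$gene_a, .data$gene_b),
           g2 = pmax(.data$gene_a, .data$gene_b)) |>
    filter(.data$g1 != .data$g2) |>
    dplyr::count(.data$g1, .data$g2, name = "n_probe_pairs")
  verts <- sort(unique(c(edges$g1, edges$g2)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = verts))
  igraph::V(g)$individually_significant <-
    igraph::V(g)$name %in% individually_significant
  g
}
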