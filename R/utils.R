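#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#' @importFrom tibble tibble as_tibble
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Enumerate all unordered pairs of features
#'
#' Returns the \eqn{\binom{m}{2}} unordered pairs of the supplied feature
#' identifiers, in lexicographic order of the canonical (sorted) pair. This is
#' the pair universe over which additive and interactive screens run; 89
#' probes yield 3916 pairs.
#'
#' @param features Character vector of distinct feature identifiers.
#' @return A tibble with columns `feature_a`, `feature_b` (with
#'   `feature_a < feature_b` in the default collation).
#' @export
#' @examples
#' enumerate_pairs(c("A", "B", "C"))
enumerate_pairs <- function(features) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicated feature identifiers", call. = FALSE)
  m <- length(features)
  if (m < 2) {
    return(tibble(feature_a = character(), feature_b = character()))
  }
  features <- sort(features)
  idx <- utils::combn(m, 2)
  tibble(feature_a = features[idx[1, ]], feature_b = features[idx[2, ]]) |>
    arrange(.data$feature_a, .data$feature_b)
}

# Canonical unordered-pair key "a|b" with a <= b.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Expression tibble -> numeric matrix with sample_id rownames.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "sample_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "sample_id")])
  if (!is.numeric(m)) stop("expression columns must be numeric", call. = FALSE)
  rownames(m) <- as.character(expr$sample_id)
  m
}

# Map feature ids to gene symbols via a (feature_id, gene) tibble; identity
# when no map is given.
genes_of <- function(features, feature_to_gene = NULL) {
  if (is.null(feature_to_gene)) return(as.character(features))
  stopifnot(all(c("feature_id", "gene") %in% names(feature_to_gene)))
  g <- feature_to_gene$gene[match(features, feature_to_gene$feature_id)]
  ifelse(is.na(g), as.character(features), as.character(g))
}

check_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || !"sample_id" %in% names(expr)) {
    stop(sprintf("`%s` must be a data frame with a sample_id column", arg), call. = FALSE)
  }
  if (anyDuplicated(expr$sample_id)) {
    stop(sprintf("duplicated sample_id in `%s`", arg), call. = FALSE)
  }
  vals <- expr[setdiff(names(expr), "sample_id")]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    stop(sprintf("non-numeric expression column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(vals)) stop("missing values are not allowed in expression matrices", call. = FALSE)
  invisible(expr)
}
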