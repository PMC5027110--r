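# Tabular readers/writers shared by all analysis stages.
#
# Canonical orientation is samples-as-rows: the first column of an expression
# file identifies the sample and every other column is one probe/transcript.
# Feature-major files are handled with `transpose = TRUE`.

guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Reads a samples-by-features table of expression values (array intensities
#' or RNA-seq read counts). The first column holds sample identifiers
#' (feature identifiers when `transpose = TRUE`); all remaining columns must
#' be numeric and complete. In `counts` mode every value must be a
#' non-negative integer.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   extension (`.csv` comma, otherwise tab) unless `delim` is given.
#' @param mode `"intensity"` for continuous values, `"counts"` for
#'   non-negative integer read counts.
#' @param transpose Set `TRUE` when the file is feature-major
#'   (features as rows, samples as columns).
#' @param delim Optional explicit field delimiter.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per feature.
#' @export
read_expression <- function(path, mode = c("intensity", "counts"),
                            transpose = FALSE, delim = NULL) {
  mode <- match.arg(mode)
  raw <- readr::read_delim(path, delim = guess_delim(path, delim),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop("expression file needs an id column plus data columns", call. = FALSE)
  names(raw)[1] <- if (transpose) "feature_id" else "sample_id"
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated %s in %s: %s",
                 names(raw)[1], path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s' row %s of %s",
                   names(vals)[j], bad %||% "?", path), call. = FALSE)
    }
  }
  if (anyNA(vals)) stop("missing expression values are not allowed", call. = FALSE)
  if (transpose) {
    m <- t(as.matrix(vals))
    colnames(m) <- ids
    out <- tibble(sample_id = colnames(raw)[-1]) |>
      dplyr::bind_cols(as_tibble(m, .name_repair = "minimal"))
  } else {
    out <- tibble(sample_id = ids) |> dplyr::bind_cols(vals)
  }
  if (anyDuplicated(names(out))) stop("duplicated feature identifiers", call. = FALSE)
  if (mode == "counts") {
    m <- expr_to_matrix(out)
    if (any(m < 0) || any(m != floor(m))) {
      bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
      stop(sprintf("counts mode requires non-negative integers; offending value at sample '%s', feature '%s'",
                   rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
    }
  }
  check_expression(out)
}

outcome_to_binary <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric outcome must be 0/1", call. = FALSE)
    return(as.integer(x))
  }
  lx <- tolower(trimws(as.character(x)))
  one <- c("1", "case", "cases", "yes", "true", "affected")
  zero <- c("0", "control", "controls", "no", "false", "unaffected")
  out <- ifelse(lx %in% one, 1L, ifelse(lx %in% zero, 0L, NA_integer_))
  if (anyNA(out)) {
    stop(sprintf("unrecognized outcome value(s): %s",
                 paste(unique(x[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read per-sample annotations (outcome and covariates)
#'
#' Reads a sample annotation table carrying the binary disease outcome and
#' any covariates used downstream (age, sex, race, family identifier, SNP
#' dosages). Column names are matched case-insensitively against common
#' synonyms; `col_map` overrides the matching.
#'
#' @param path Path to a delimited annotation table with a header row.
#' @param col_map Optional named character vector mapping canonical names
#'   (`sample_id`, `outcome`, `age`, `sex`, `race`, `family_id`) to the
#'   file's column names.
#' @param delim Optional explicit field delimiter.
#' @return A tibble with `sample_id`, integer `outcome` in \{0, 1\}, and any
#'   further columns found (categoricals kept as character).
#' @export
read_annotations <- function(path, col_map = NULL, delim = NULL) {
  raw <- readr::read_delim(path, delim = guess_delim(path, delim),
                           show_col_types = FALSE, progress = FALSE)
  synonyms <- list(
    sample_id = c("sample_id", "sample", "id", "subject_id"),
    outcome   = c("outcome", "status", "case", "mi", "phenotype"),
    age       = c("age", "age_years"),
    sex       = c("sex", "gender"),
    race      = c("race", "ancestry"),
    family_id = c("family_id", "family", "famid", "pedigree")
  )
  lows <- tolower(names(raw))
  resolve <- function(canon) {
    if (!is.null(col_map) && canon %in% names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (is.na(j)) stop(sprintf("column '%s' (mapped to %s) not found", col_map[[canon]], canon),
                         call. = FALSE)
      return(j)
    }
    j <- match(synonyms[[canon]], lows)
    j[!is.na(j)][1]
  }
  js <- sapply(names(synonyms), resolve)
  if (is.na(js[["sample_id"]])) stop("no sample identifier column found", call. = FALSE)
  if (is.na(js[["outcome"]])) stop("no outcome column found", call. = FALSE)
  found <- js[!is.na(js)]
  out <- raw[unname(found)]
  names(out) <- names(found)
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) stop("duplicated sample_id in annotations", call. = FALSE)
  out$outcome <- outcome_to_binary(out$outcome)
  if ("family_id" %in% names(out)) out$family_id <- as.character(out$family_id)
  extra <- raw[setdiff(seq_along(raw), unname(found))]
  as_tibble(dplyr::bind_cols(out, extra))
}

#' Collect fitted models into one long results table
#'
#' Flattens a list of fitted model objects (see [fit_single()], [fit_pair()],
#' [fit_path_model()]) or resample summaries into a long tibble with one row
#' per model term, deterministically ordered by feature identifiers then
#' term.
#'
#' @param results A single fit/summary or a list of them.
#' @return A tibble with columns `model_tag`, `features`, `term`, `estimate`,
#'   `std_error`, `p_value`, `converged`, `n_used`, plus
#'   `fraction_significant` and `median_p` for resample summaries.
#' @export
results_table <- function(results) {
  if (inherits(results, c("coexpair_fit", "resample_summary"))) results <- list(results)
  empty <- tibble(model_tag = character(), features = character(),
                  term = character(), estimate = numeric(),
                  std_error = numeric(), p_value = numeric(),
                  fraction_significant = numeric(), median_p = numeric(),
                  converged = logical(), n_used = integer())
  if (!length(results)) return(empty)
  rows <- purrr::map(results, function(r) {
    if (inherits(r, "coexpair_fit")) {
      tibble(model_tag = r$model_tag,
             features = paste(r$features, collapse = "|"),
             term = r$terms$term,
             estimate = r$terms$estimate,
             std_error = r$terms$std_error,
             p_value = r$terms$p_value,
             fraction_significant = NA_real_, median_p = NA_real_,
             converged = r$converged, n_used = r$n_used)
    } else if (inherits(r, "resample_summary")) {
      s <- r$summary
      tibble(model_tag = r$model_tag,
             features = paste(r$features, collapse = "|"),
             term = s$term, estimate = s$mean_estimate,
             std_error = NA_real_, p_value = NA_real_,
             fraction_significant = s$fraction_significant,
             median_p = s$median_p,
             converged = TRUE, n_used = r$n_resamples)
    } else {
      stop("unsupported result object of class ", paste(class(r), collapse = "/"),
           call. = FALSE)
    }
  })
  bind_rows(rows) |> arrange(.data$features, .data$model_tag, .data$term)
}

#' Write model results to a TSV file
#'
#' @param results A fit object, resample summary, or list of them.
#' @param path Output path ('.tsv').
#' @return The written tibble, invisibly.
#' @export
write_results <- function(results, path) {
  tab <- results_table(results)
  readr::write_tsv(tab, path)
  invisible(tab)
}

#' Write a co-expression network to disk
#'
#' Writes the edge table of a thresholded consensus network either as a TSV
#' edge list (columns `feature_a`, `feature_b`, `gene_a`, `gene_b`,
#' `frequency`, `retained`) or as GraphML with the same edge attributes.
#'
#' @param edges An edge tibble as produced by [threshold_edges()].
#' @param path Output file path.
#' @param format `"edge_list"` (TSV) or `"graphml"`.
#' @return `path`, invisibly.
#' @seealso [read_network()] for the edge-list round trip.
#' @export
write_network <- function(edges, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  need <- c("feature_a", "feature_b", "gene_a", "gene_b", "frequency", "retained")
  if (!all(need %in% names(edges))) {
    stop("edge table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  edges <- edges |> arrange(.data$feature_a, .data$feature_b)
  if (format == "edge_list") {
    readr::write_tsv(edges[need], path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges |> select("feature_a", "feature_b", "gene_a", "gene_b",
                      "frequency", "retained"),
      directed = FALSE
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list network written by [write_network()]
#'
#' @param path Path to a TSV edge list.
#' @return The edge tibble.
#' @export
read_network <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    feature_a = "c", feature_b = "c", gene_a = "c",
                    gene_b = "c", frequency = "d", retained = "l"
                  ))
}
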