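#' Read a taxa-by-sample count table from TSV
#'
#' Reads a tab-separated count table with one header row of sample ids and a
#' first column of feature ids (the layout produced by mOTUs-style profilers).
#' Counts must be non-negative; fractional values are either rejected or
#' floored depending on `strict`.
#'
#' @param path path to a TSV file (UTF-8).
#' @param features_in_rows logical; if `FALSE` the table on disk is
#'   samples x features and is transposed after reading. Default `TRUE`.
#' @param strict logical; if `TRUE` (default) non-integer values are an error,
#'   otherwise they are floored to integers.
#' @return an integer matrix (features x samples) with feature rownames and
#'   sample colnames.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(matrix(1:6, 3, dimnames = list(paste0("f", 1:3), paste0("s", 1:2))),
#'   tf, sep = "\t", quote = FALSE, col.names = NA
#' )
#' cm <- read_count_table(tf)
#' dim(cm)
read_count_table <- function(path, features_in_rows = TRUE, strict = TRUE) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t", row.names = NULL,
    check.names = FALSE, stringsAsFactors = FALSE, comment.char = ""
  )
  if (ncol(tab) < 2) stop("malformed count table: need an id column plus >= 1 sample", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature ids in count table", call. = FALSE)
  body <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("malformed count table: non-numeric body", call. = FALSE)
  rownames(body) <- ids
  if (anyDuplicated(colnames(body))) stop("duplicated sample ids in count table", call. = FALSE)
  if (!features_in_rows) body <- t(body)
  if (any(body < 0)) stop("count table contains negative values", call. = FALSE)
  if (any(body != floor(body))) {
    if (strict) stop("count table contains non-integer values (set strict = FALSE to floor)", call. = FALSE)
    body <- floor(body)
  }
  storage.mode(body) <- "integer"
  assert_count_matrix(body)
  body
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_table()]: feature ids in the first column
#' (header `feature_id`), sample ids as the remaining column names.
#'
#' @param cm integer count matrix (features x samples).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  assert_count_matrix(cm)
  df <- data.frame(feature_id = rownames(cm), cm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter features on prevalence and maximum relative abundance
#'
#' Keeps features observed in at least `prev_min` of samples whose maximum
#' per-sample relative abundance reaches `relab_max_min` — the standard
#' pre-filter applied to taxonomic profiles before simulation and testing.
#'
#' @param cm count matrix (features x samples).
#' @param prev_min minimum prevalence (fraction of samples with a non-zero
#'   count), default 0.05.
#' @param relab_max_min minimum of the per-feature maximum relative abundance,
#'   default 1e-4.
#' @return the filtered count matrix (same samples, subset of features).
#' @export
filter_features <- function(cm, prev_min = 0.05, relab_max_min = 1e-4) {
  assert_count_matrix(cm)
  stopifnot(prev_min >= 0, prev_min <= 1, relab_max_min >= 0, relab_max_min <= 1)
  totals <- colSums(cm)
  relab <- sweep(cm, 2, pmax(totals, 1), "/")
  prev <- rowMeans(cm > 0)
  keep <- prev >= prev_min & apply(relab, 1, max) >= relab_max_min
  if (prev_min > 0) keep <- keep & rowSums(cm > 0) > 0
  if (!any(keep)) {
    stop(sprintf(
      "no features pass filtering (prev_min = %g, relab_max_min = %g); max prevalence observed = %g",
      prev_min, relab_max_min, max(prev)
    ), call. = FALSE)
  }
  cm[keep, , drop = FALSE]
}

#' Summarise a count matrix as a tibble
#'
#' One row per feature with prevalence, mean/max relative abundance and
#' variance of log10 relative abundance — convenient for piping into dplyr.
#'
#' @param cm count matrix.
#' @param pseudocount pseudocount added to relative abundances before log10.
#' @return a tibble with columns `feature_id`, `prevalence`, `mean_relab`,
#'   `max_relab`, `log_var`.
#' @export
feature_summary <- function(cm, pseudocount = 1e-5) {
  assert_count_matrix(cm)
  relab <- sweep(cm, 2, pmax(colSums(cm), 1), "/")
  lg <- log10(relab + pseudocount)
  tibble::tibble(
    feature_id = rownames(cm),
    prevalence = unname(rowMeans(cm > 0)),
    mean_relab = unname(rowMeans(relab)),
    max_relab = unname(apply(relab, 1, max)),
    log_var = unname(apply(lg, 1, stats::var))
  )
}
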