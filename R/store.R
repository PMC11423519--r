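#' Open (or create) a simulation store
#'
#' A directory-backed hierarchical store holding the original table, every
#' simulated repetition with its full parameterisation and seed, the shared
#' test indices, and per-method results. Everything is plain text (TSV bodies,
#' JSON parameter records) so a store written on one machine reads identically
#' on any other, and every DA method consumes byte-identical inputs.
#'
#' Layout: `original/` (input table), `sim/<key>/` (counts, labels, truth,
#' params), `test_idx/` (long-format index table), `results/<method>.tsv`.
#'
#' @param path directory path.
#' @param create create the directory if absent (default `TRUE`).
#' @return an object of class `sim_store`.
#' @export
sim_store <- function(path, create = TRUE) {
  if (!dir.exists(path)) {
    if (!create) stop("store does not exist: ", path, call. = FALSE)
    dir.create(path, recursive = TRUE)
  }
  structure(list(path = normalizePath(path)), class = "sim_store")
}

#' @export
print.sim_store <- function(x, ...) {
  cat(sprintf(
    "<sim_store> %s\n  simulations: %d; results: %d\n",
    x$path, length(store_keys(x)), length(store_keys(x, "results"))
  ))
  invisible(x)
}

store_path <- function(store, ...) file.path(store$path, ...)

#' List keys stored under a store group
#'
#' @param store a `sim_store`.
#' @param what one of `"sim"` or `"results"`.
#' @return character vector of keys.
#' @export
store_keys <- function(store, what = c("sim", "results")) {
  what <- match.arg(what)
  dir <- store_path(store, what)
  if (!dir.exists(dir)) return(character())
  if (what == "results") sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$")) else list.files(dir)
}

#' Save the original (baseline) count table into a store
#' @param store a `sim_store`.
#' @param cm count matrix.
#' @return the store, invisibly.
#' @export
store_save_original <- function(store, cm) {
  dir.create(store_path(store, "original"), showWarnings = FALSE)
  write_count_table(cm, store_path(store, "original", "counts.tsv"))
  invisible(store)
}

#' Load the original count table from a store
#' @param store a `sim_store`.
#' @return the count matrix.
#' @export
store_load_original <- function(store) {
  f <- store_path(store, "original", "counts.tsv")
  if (!file.exists(f)) stop("store has no original table", call. = FALSE)
  read_count_table(f)
}

#' Save a simulated dataset under a key
#'
#' @param store a `sim_store`.
#' @param dataset a [sim_dataset()].
#' @param key unique key (e.g. `"ab2_prev0.2_rep3"`).
#' @param overwrite allow replacing an existing key (default `FALSE`).
#' @return the store, invisibly.
#' @export
save_simulation <- function(store, dataset, key, overwrite = FALSE) {
  stopifnot(inherits(store, "sim_store"), inherits(dataset, "sim_dataset"))
  if (grepl("[/\\\\]", key)) stop("key must not contain path separators", call. = FALSE)
  dir <- store_path(store, "sim", key)
  if (dir.exists(dir) && !overwrite) stop("key already exists in store: ", key, call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  lab <- data.frame(
    sample_id = colnames(dataset$counts),
    label = as.character(dataset$labels),
    confounder = if (is.null(dataset$confounder)) NA_character_ else as.character(dataset$confounder)
  )
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$params, file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(store)
}

#' Load a simulated dataset from a store
#'
#' @param store a `sim_store`.
#' @param key key used at save time.
#' @return the [sim_dataset()]; `save_simulation()` then `load_simulation()`
#'   is the identity on counts, labels, confounder, truth and parameters.
#' @export
load_simulation <- function(store, key) {
  dir <- store_path(store, "sim", key)
  if (!dir.exists(dir)) stop("no simulation stored under key: ", key, call. = FALSE)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  lab <- utils::read.table(file.path(dir, "labels.tsv"),
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "character"), na.strings = "NA"
  )
  truth <- tibble::as_tibble(utils::read.table(file.path(dir, "truth.tsv"),
    header = TRUE, sep = "\t",
    colClasses = c("character", "integer", "numeric", "numeric", "numeric", "numeric", "logical")
  ))
  params <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  conf <- if (all(is.na(lab$confounder))) NULL else lab$confounder
  sim_dataset(counts, lab$label, truth = truth, confounder = conf, params = params)
}

#' Save / load shared test indices
#'
#' Test indices are a long tibble (`sample_size`, `subsample`, `position`)
#' listing, for each testing repetition, the sample positions every DA method
#' must use.
#'
#' @param store a `sim_store`.
#' @param indices tibble from [generate_test_indices()].
#' @return the store (save) or the indices tibble (load).
#' @export
save_test_indices <- function(store, indices) {
  stopifnot(all(c("sample_size", "subsample", "position") %in% names(indices)))
  dir.create(store_path(store, "test_idx"), showWarnings = FALSE)
  utils::write.table(indices, store_path(store, "test_idx", "indices.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(store)
}

#' @rdname save_test_indices
#' @export
load_test_indices <- function(store) {
  f <- store_path(store, "test_idx", "indices.tsv")
  if (!file.exists(f)) stop("store has no test indices", call. = FALSE)
  tibble::as_tibble(utils::read.table(f, header = TRUE, sep = "\t"))
}

#' Save / load per-method result tables
#'
#' Results are long tibbles; saving appends nothing — each method key holds
#' one table, so a re-run with `overwrite = TRUE` replaces it atomically.
#'
#' @param store a `sim_store`.
#' @param results a tibble of results.
#' @param method method key (file stem).
#' @param overwrite replace an existing table (default `TRUE`).
#' @return the store (save) or the results tibble (load).
#' @export
save_results <- function(store, results, method, overwrite = TRUE) {
  dir.create(store_path(store, "results"), showWarnings = FALSE)
  f <- store_path(store, "results", paste0(method, ".tsv"))
  if (file.exists(f) && !overwrite) stop("results already stored for method: ", method, call. = FALSE)
  utils::write.table(results, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(store)
}

#' @rdname save_results
#' @export
load_results <- function(store, method) {
  f <- store_path(store, "results", paste0(method, ".tsv"))
  if (!file.exists(f)) stop("no results stored for method: ", method, call. = FALSE)
  tibble::as_tibble(utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}
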