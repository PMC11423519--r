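#' Construct a simulated dataset
#'
#' Bundles a count matrix with its mock group labels, optional confounder
#' labels, the implanted ground truth, and the parameters that produced it.
#' All downstream testing and evaluation consumes this container.
#'
#' @param counts integer count matrix (features x samples).
#' @param labels per-sample group labels (two levels).
#' @param truth ground-truth tibble as produced by the implantation engine;
#'   columns `feature_id`, `target_group`, `abundance_scale`, `prev_shift`,
#'   `gfc`, `prev_diff`, `rejected`.
#' @param confounder optional per-sample binary confounder labels.
#' @param params named list of simulation parameters (including the seed).
#' @return an object of class `sim_dataset`.
#' @export
sim_dataset <- function(counts, labels, truth = empty_ground_truth(),
                        confounder = NULL, params = list()) {
  assert_count_matrix(counts, "counts")
  labels <- as_group_factor(labels, n = ncol(counts))
  if (!is.null(confounder)) confounder <- as_group_factor(confounder, n = ncol(counts))
  stopifnot(is.data.frame(truth))
  structure(
    list(
      counts = counts, labels = labels, confounder = confounder,
      truth = tibble::as_tibble(truth), params = params
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d features x %d samples (groups %s)\n",
    nrow(x$counts), ncol(x$counts), paste(table(x$labels), collapse = "/")
  ))
  n_true <- sum(!x$truth$rejected)
  cat(sprintf(
    "  ground truth: %d implanted features (%d rejected)%s\n",
    n_true, sum(x$truth$rejected),
    if (is.null(x$confounder)) "" else "; confounder label present"
  ))
  invisible(x)
}

#' Implanted (non-rejected) ground-truth feature ids
#' @param ds a `sim_dataset`.
#' @return character vector of feature ids.
#' @export
truth_features <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  ds$truth$feature_id[!ds$truth$rejected]
}

empty_ground_truth <- function() {
  tibble::tibble(
    feature_id = character(), target_group = integer(),
    abundance_scale = numeric(), prev_shift = numeric(),
    gfc = numeric(), prev_diff = numeric(), rejected = logical()
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ground truth of a simulated dataset
#'
#' @param x a `sim_dataset`.
#' @param ... unused.
#' @return the ground-truth tibble (one row per selected feature, including
#'   rejected ones, flagged in `rejected`).
#' @export
tidy.sim_dataset <- function(x, ...) x$truth

#' One-row summary of a simulated dataset
#'
#' @param x a `sim_dataset`.
#' @param ... unused.
#' @return a one-row tibble with dimensions, sparsity and truth counts.
#' @export
glance.sim_dataset <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$counts),
    n_samples = ncol(x$counts),
    sparsity = mean(x$counts == 0),
    n_truth = sum(!x$truth$rejected),
    n_rejected = sum(x$truth$rejected),
    has_confounder = !is.null(x$confounder)
  )
}
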