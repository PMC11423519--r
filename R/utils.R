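# Internal helpers: seed derivation and small numeric utilities.

#' Derive a child seed from a master seed and a path of integer indices
#'
#' A single master seed is expanded deterministically into per-task seeds so
#' that any repeat / sample-size / subsample task can be reproduced in
#' isolation. Uses a splitmix-style integer mix reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the task (e.g. repeat, size, subsample).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  idx <- c(master, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in seq_along(idx)) {
    # mix each index with a distinct odd multiplier; all arithmetic kept < 2^53
    h <- (h * 69069 + (as.numeric(idx[k]) %% m) * (2 * k + 1) + 0x9E37) %% m
    h <- (h * 48271) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# round half up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count_matrix <- function(cm, arg = "cm") {
  if (!is.matrix(cm) || !is.numeric(cm)) {
    stop(sprintf("`%s` must be a numeric matrix (features x samples)", arg), call. = FALSE)
  }
  if (any(cm < 0)) stop(sprintf("`%s` contains negative values", arg), call. = FALSE)
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    stop(sprintf("`%s` must carry feature rownames and sample colnames", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(cm)) || anyDuplicated(colnames(cm))) {
    stop(sprintf("`%s` has duplicated feature or sample ids", arg), call. = FALSE)
  }
  invisible(cm)
}

# binary group labels as a factor with levels c("1", "2"); accepts factor,
# character, or 0/1-coded numerics
as_group_factor <- function(labels, n = NULL) {
  g <- factor(labels)
  if (nlevels(g) != 2) stop("group labels must take exactly two values", call. = FALSE)
  if (!is.null(n) && length(g) != n) stop("label length does not match sample count", call. = FALSE)
  g
}
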