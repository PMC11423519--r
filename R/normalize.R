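#' Rarefy a count matrix to a common depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric, via
#' `vegan::rrarefy`) so each sample whose total exceeds `depth` ends up with
#' exactly `depth` reads. Samples at or below the target depth are left
#' unchanged rather than dropped, so shared test indices stay valid.
#'
#' @param cm count matrix (features x samples).
#' @param depth target depth: a single number, a per-sample vector, or
#'   `"q25"` (default) for the 25th percentile of sample totals.
#' @param seed integer seed.
#' @return an integer count matrix of the same shape; no entry ever
#'   increases and zeros stay zero.
#' @export
rarefy_counts <- function(cm, depth = "q25", seed = 1L) {
  assert_count_matrix(cm)
  totals <- colSums(cm)
  if (identical(depth, "q25")) {
    depth <- stats::quantile(totals, probs = 0.25, type = 7, names = FALSE)
  }
  stopifnot(all(depth > 0))
  depth <- rep_len(depth, ncol(cm))
  out <- cm
  above <- which(totals > depth)
  if (length(above)) {
    withr::with_seed(seed, {
      # rrarefy warns whenever the smallest non-zero entry exceeds 1, which is
      # routine for deep profiles; the below-depth case never reaches it
      sub <- t(suppressWarnings(
        vegan::rrarefy(t(cm[, above, drop = FALSE]), sample = depth[above])
      ))
    })
    out[, above] <- sub
  }
  storage.mode(out) <- "integer"
  out
}

#' Normalize / transform a count matrix before DA testing
#'
#' The preprocessing transformations applied ahead of the rank- and
#' linear-model-based tests:
#' \describe{
#'   \item{TSS}{total sum scaling; every column sums to 1.}
#'   \item{TSS.log}{`log10(TSS + pseudocount)`.}
#'   \item{TSS.arcsin}{`asin(sqrt(TSS))`.}
#'   \item{clr}{centered log-ratio on `count + clr_pseudocount`, centered by
#'     the per-sample mean log over all features.}
#'   \item{rclr}{robust clr: log of non-zero relative abundances centered by
#'     the per-sample geometric mean over non-zero entries; zeros map to 0.}
#'   \item{rarefaction}{subsampling to the 25th percentile depth (counts).}
#'   \item{rarefaction-TSS, rarefaction-TSS.log}{rarefaction followed by the
#'     corresponding transformation.}
#' }
#'
#' @param cm count matrix (features x samples).
#' @param method transformation name (see above).
#' @param pseudocount pseudocount on relative abundances for `TSS.log`
#'   (default 1e-5).
#' @param clr_pseudocount pseudocount on counts for `clr` (default 1).
#' @param depth rarefaction depth, see [rarefy_counts()].
#' @param seed seed for the rarefaction variants.
#' @return a numeric matrix (features x samples); integer counts for the
#'   plain `rarefaction` method.
#' @export
#' @examples
#' cm <- generate_baseline(baseline_spec(n_features = 40, n_samples = 20, seed = 5))
#' colSums(normalize_counts(cm, "TSS"))[1:3]
normalize_counts <- function(cm, method = c(
                               "TSS", "TSS.log", "TSS.arcsin", "clr", "rclr",
                               "rarefaction", "rarefaction-TSS", "rarefaction-TSS.log"
                             ),
                             pseudocount = 1e-5, clr_pseudocount = 1,
                             depth = "q25", seed = 1L) {
  assert_count_matrix(cm)
  method <- match.arg(method)
  if (startsWith(method, "rarefaction")) {
    rar <- rarefy_counts(cm, depth = depth, seed = seed)
    return(switch(method,
      "rarefaction" = rar,
      "rarefaction-TSS" = normalize_counts(rar, "TSS"),
      "rarefaction-TSS.log" = normalize_counts(rar, "TSS.log", pseudocount = pseudocount)
    ))
  }
  totals <- colSums(cm)
  if (method %in% c("TSS", "TSS.log", "TSS.arcsin", "rclr") && any(totals == 0)) {
    stop("cannot total-sum scale: sample(s) with zero total counts", call. = FALSE)
  }
  switch(method,
    "TSS" = sweep(cm, 2, totals, "/"),
    "TSS.log" = log10(sweep(cm, 2, totals, "/") + pseudocount),
    "TSS.arcsin" = asin(sqrt(sweep(cm, 2, totals, "/"))),
    "clr" = {
      lg <- log(cm + clr_pseudocount)
      sweep(lg, 2, colMeans(lg), "-")
    },
    "rclr" = {
      tss <- sweep(cm, 2, totals, "/")
      out <- matrix(0, nrow(cm), ncol(cm), dimnames = dimnames(cm))
      for (j in seq_len(ncol(cm))) {
        nz <- tss[, j] > 0
        out[nz, j] <- log(tss[nz, j]) - mean(log(tss[nz, j]))
      }
      out
    }
  )
}
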