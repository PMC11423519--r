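#' Phi coefficient of two binary variables
#'
#' The standard 2x2 contingency-table association measure,
#' `phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`, in `[-1, 1]`.
#'
#' @param x,y binary vectors (logical, 0/1, or two-level factors) of equal
#'   length. The "positive" level is the larger value / second factor level.
#' @return a single numeric phi.
#' @export
#' @examples
#' phi_coefficient(rep(0:1, each = 50), rep(0:1, each = 50)) # 1
phi_coefficient <- function(x, y) {
  to01 <- function(v) {
    f <- factor(v)
    if (nlevels(f) == 1) stop("phi coefficient undefined for a constant variable", call. = FALSE)
    if (nlevels(f) != 2) stop("phi coefficient requires binary variables", call. = FALSE)
    as.integer(f) - 1L
  }
  x <- to01(x)
  y <- to01(y)
  stopifnot(length(x) == length(y))
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  denom <- sqrt(prod(c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)))
  (n11 * n00 - n10 * n01) / denom
}

#' Implant an independent confounder signal
#'
#' Repeats the implantation procedure for a freshly drawn, independent binary
#' confounder label, on a feature set disjoint from the main ground truth —
#' dividing the samples into four theoretical strata (label x confounder).
#' Before any biased resampling the two labels are independent by
#' construction.
#'
#' @param ds a [sim_dataset()] carrying the main signal.
#' @param fraction fraction of all features to implant for the confounder
#'   (default 0.1).
#' @param scale,shift confounder effect sizes (as in [implant_signal()]).
#' @param seed integer seed.
#' @param reject_gfc,rounding as in [implant_signal()].
#' @return a `confounded_dataset` (a `sim_dataset` with `$confounder` set and
#'   a `$confounder_truth` tibble disjoint from the main truth).
#' @export
implant_confounder <- function(ds, fraction = 0.1, scale = 2, shift = 0.2, seed = 1L,
                               reject_gfc = 0.001, rounding = "half_up") {
  stopifnot(inherits(ds, "sim_dataset"))
  cm <- ds$counts
  n <- ncol(cm)
  used <- ds$truth$feature_id
  pool <- setdiff(rownames(cm), used)
  k <- round(fraction * nrow(cm))
  if (length(pool) < k) stop("feature pool exhausted: not enough features outside the main truth", call. = FALSE)
  conf <- split_groups(cm, seed = child_seed(seed, 21L))
  withr::with_seed(child_seed(seed, 22L), features <- sample(pool, k))
  direction <- target_directions(features, balanced = TRUE)
  sub <- build_implantation(cm, conf, features, child_seed(seed, 23L),
    scale = scale, shift = shift, direction = direction,
    reject_gfc = reject_gfc, rounding = rounding, params = ds$params
  )
  out <- sim_dataset(sub$counts, ds$labels,
    truth = ds$truth, confounder = conf,
    params = c(ds$params[setdiff(names(ds$params), c("conf_scale", "conf_shift"))],
      list(conf_scale = scale, conf_shift = shift, conf_seed = seed)
    )
  )
  out$confounder_truth <- sub$truth
  class(out) <- c("confounded_dataset", class(out))
  out
}

#' @export
print.confounded_dataset <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "  confounder truth: %d implanted features (%d rejected)\n",
    sum(!x$confounder_truth$rejected), sum(x$confounder_truth$rejected)
  ))
  invisible(x)
}

# two-cell largest-remainder split of `total` into (p, 1-p)
quota2 <- function(total, p) {
  a <- total * p
  k <- c(floor(a), floor(total - a))
  rem <- total - sum(k)
  if (rem > 0) {
    frac <- c(a - floor(a), (total - a) - floor(total - a))
    k[which.max(frac)] <- k[which.max(frac)] + rem
  }
  k
}

#' Draw a biased case-control subsample with a target label-confounder phi
#'
#' Samples `n/2` cases and `n/2` controls without replacement, with stratum
#' quotas tuned so the expected phi coefficient between the case-control and
#' confounder labels equals `bias`: among cases the confounder-positive
#' fraction is `(1 + bias)/2`, among controls `(1 - bias)/2` (largest-
#' remainder rounding). `bias = 0` draws all four strata proportionally (no
#' confounding); `bias = 1` makes label and confounder coincide.
#'
#' @param cd a `confounded_dataset` (or any `sim_dataset` with `$confounder`).
#' @param n even total subsample size.
#' @param bias confounder strength in `[0, 1]`.
#' @param seed integer seed.
#' @return tibble with one row per drawn sample: `position` (column index),
#'   `label`, `confounder`.
#' @export
biased_resample <- function(cd, n, bias, seed = 1L) {
  stopifnot(inherits(cd, "sim_dataset"), !is.null(cd$confounder))
  stopifnot(n %% 2 == 0, bias >= 0, bias <= 1)
  lab <- cd$labels
  conf <- cd$confounder
  half <- n %/% 2
  strata <- list(
    "case/conf+" = which(lab == "2" & conf == "2"),
    "case/conf-" = which(lab == "2" & conf == "1"),
    "ctrl/conf+" = which(lab == "1" & conf == "2"),
    "ctrl/conf-" = which(lab == "1" & conf == "1")
  )
  q_case <- quota2(half, (1 + bias) / 2) # (conf+, conf-)
  q_ctrl <- quota2(half, (1 - bias) / 2)
  quota <- c(q_case, q_ctrl)
  names(quota) <- names(strata)
  avail <- lengths(strata)
  short <- quota > avail
  if (any(short)) {
    # bias at which the binding increasing quotas would just fit
    max_b <- min(1, 4 * avail[["case/conf+"]] / n - 1, 4 * avail[["ctrl/conf-"]] / n - 1)
    stop(sprintf(
      "stratum %s cannot satisfy its quota (%d needed, %d available); maximum feasible bias ~ %.2f",
      names(quota)[short][1], quota[short][1], avail[short][1], max(0, max_b)
    ), call. = FALSE)
  }
  withr::with_seed(seed, {
    picks <- unlist(purrr::map2(strata, quota, function(s, k) {
      if (k == 0) integer() else if (length(s) == 1) s else sample(s, k)
    }), use.names = FALSE)
  })
  tibble::tibble(
    position = picks,
    label = as.character(lab[picks]),
    confounder = as.character(conf[picks])
  )
}

#' Combine two count tables into one study-labelled table
#'
#' Column-concatenates two studies over the union of their feature ids
#' (absent features zero-filled). The study-of-origin label can serve as the
#' confounder in [biased_resample()], mimicking batch effects in a
#' meta-analysis.
#'
#' @param cm1,cm2 count matrices with disjoint sample ids.
#' @return list with `counts` (features x all samples) and `study` (factor
#'   `"1"`/`"2"` of origin).
#' @export
combine_studies <- function(cm1, cm2) {
  assert_count_matrix(cm1, "cm1")
  assert_count_matrix(cm2, "cm2")
  if (length(intersect(colnames(cm1), colnames(cm2)))) {
    stop("sample id collision between the two studies", call. = FALSE)
  }
  feats <- union(rownames(cm1), rownames(cm2))
  pad <- function(cm) {
    out <- matrix(0L, length(feats), ncol(cm), dimnames = list(feats, colnames(cm)))
    out[rownames(cm), ] <- cm
    out
  }
  counts <- cbind(pad(cm1), pad(cm2))
  storage.mode(counts) <- "integer"
  list(
    counts = counts,
    study = factor(rep(c("1", "2"), c(ncol(cm1), ncol(cm2))), levels = c("1", "2"))
  )
}
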