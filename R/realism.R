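#' Sparsity and log-variance summaries of a count matrix
#'
#' The two scalar realism axes: per-sample sparsity (fraction of zero
#' features) and per-feature variance of log10 relative abundance.
#'
#' @param cm count matrix.
#' @param pseudocount pseudocount on relative abundances before log10.
#' @return list with tibbles `sample` (`sample_id`, `sparsity`) and
#'   `feature` (`feature_id`, `mean_relab`, `log_var`).
#' @export
sparsity_and_variance <- function(cm, pseudocount = 1e-5) {
  assert_count_matrix(cm)
  fs <- feature_summary(cm, pseudocount = pseudocount)
  list(
    sample = tibble::tibble(
      sample_id = colnames(cm),
      sparsity = unname(colMeans(cm == 0))
    ),
    feature = fs[, c("feature_id", "mean_relab", "log_var")]
  )
}

#' Log-Euclidean distances between samples
#'
#' Euclidean distance on `log10(TSS + pseudocount)` profiles — the sample
#' space in which ordination and PERMANOVA comparisons are run.
#'
#' @param cm count matrix.
#' @param pseudocount pseudocount on relative abundances (default 1e-5).
#' @return a `dist` over samples.
#' @export
log_euclidean_dist <- function(cm, pseudocount = 1e-5) {
  assert_count_matrix(cm)
  stats::dist(t(log10(sweep(cm, 2, pmax(colSums(cm), 1), "/") + pseudocount)))
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Tests group separation in distance space via the permutation pseudo-F
#' (vegan's `adonis2`): `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param d a `dist` or square symmetric distance matrix.
#' @param groups group labels (>= 2 levels).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return one-row tibble with `pseudo_f`, `r2`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  if (is.matrix(d)) {
    stopifnot(nrow(d) == ncol(d), isSymmetric(unname(d)))
    d <- stats::as.dist(d)
  }
  stopifnot(inherits(d, "dist"))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("permanova needs at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least two samples", call. = FALSE)
  stopifnot(length(groups) == attr(d, "Size"))
  df <- data.frame(groups = groups)
  fit <- withr::with_seed(seed, vegan::adonis2(d ~ groups, data = df, permutations = n_perm))
  tibble::tibble(
    pseudo_f = fit$F[1],
    r2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm
  )
}

# stratified fold assignment: every class spread as evenly as possible
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# rank-based AUROC of scores for a binary truth (ties count 1/2)
rank_auroc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes non-empty", call. = FALSE)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Can a LASSO classifier tell simulated from real samples?
#'
#' Concatenates the real and simulated tables, z-standardises log10 relative
#' abundances per feature, and evaluates an L1-penalised logistic regression
#' by repeated stratified k-fold cross-validation (nested: the penalty is
#' chosen by an inner `cv.glmnet` on each training fold). An AUROC near 0.5
#' means the simulation is indistinguishable from the real data in this
#' feature space; parametric simulations of sparse data typically score
#' > 0.9.
#'
#' @param real,sim count matrices over a shared feature universe (intersected
#'   on feature ids).
#' @param folds outer folds (default 10).
#' @param repeats outer repetitions (default 10).
#' @param seed integer seed.
#' @param pseudocount pseudocount on relative abundances (default 1e-5).
#' @return mean held-out AUROC over repetitions.
#' @export
real_vs_sim_auroc <- function(real, sim, folds = 10, repeats = 10, seed = 1L,
                              pseudocount = 1e-5) {
  assert_count_matrix(real, "real")
  assert_count_matrix(sim, "sim")
  feats <- intersect(rownames(real), rownames(sim))
  if (length(feats) < 2) stop("real and sim share too few features", call. = FALSE)
  ratio <- ncol(real) / ncol(sim)
  if (ratio > 100 || ratio < 1 / 100) stop("class imbalance exceeds 100:1", call. = FALSE)
  lg <- function(cm) log10(sweep(cm, 2, pmax(colSums(cm), 1), "/") + pseudocount)
  x <- cbind(lg(real[feats, , drop = FALSE]), lg(sim[feats, , drop = FALSE]))
  colnames(x) <- NULL
  y <- factor(rep(c("real", "sim"), c(ncol(real), ncol(sim))))
  # per-feature z-standardisation; constant features carry no signal
  sds <- apply(x, 1, stats::sd)
  keep <- sds > 0
  x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sds[keep]
  xt <- t(x)
  aurocs <- withr::with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      fold <- stratified_folds(y, folds)
      pred <- numeric(length(y))
      for (k in seq_len(folds)) {
        tr <- fold != k
        cvfit <- glmnet::cv.glmnet(xt[tr, , drop = FALSE], y[tr],
          family = "binomial", alpha = 1, nfolds = 5, nlambda = 25,
          standardize = FALSE, thresh = 1e-5
        )
        pred[!tr] <- stats::predict(cvfit, xt[!tr, , drop = FALSE],
          s = "lambda.min", type = "response"
        )[, 1]
      }
      rank_auroc(pred, y == "sim")
    }, numeric(1))
  })
  mean(aurocs)
}

#' Realism report for a simulated dataset against its baseline
#'
#' Bundles the sparsity/variance summaries, the log-Euclidean PERMANOVA and
#' the real-vs-simulated classifier AUROC into one tibble row.
#'
#' @param real baseline count matrix.
#' @param sim simulated count matrix.
#' @param n_perm PERMANOVA permutations (default 199).
#' @param folds,repeats classifier cross-validation scheme.
#' @param seed integer seed.
#' @return one-row tibble: mean sparsities, median log-variances, PERMANOVA
#'   F and p, classifier AUROC.
#' @export
realism_report <- function(real, sim, n_perm = 199, folds = 5, repeats = 2, seed = 1L) {
  sv_r <- sparsity_and_variance(real)
  sv_s <- sparsity_and_variance(sim)
  feats <- intersect(rownames(real), rownames(sim))
  comb <- cbind(real[feats, , drop = FALSE], sim[feats, , drop = FALSE])
  colnames(comb) <- sprintf("cmb_%04d", seq_len(ncol(comb)))
  origin <- rep(c("real", "sim"), c(ncol(real), ncol(sim)))
  pmv <- permanova(log_euclidean_dist(comb), origin, n_perm = n_perm, seed = child_seed(seed, 31L))
  auc <- real_vs_sim_auroc(real, sim, folds = folds, repeats = repeats, seed = child_seed(seed, 32L))
  tibble::tibble(
    sparsity_real = mean(sv_r$sample$sparsity),
    sparsity_sim = mean(sv_s$sample$sparsity),
    log_var_real = stats::median(sv_r$feature$log_var),
    log_var_sim = stats::median(sv_s$feature$log_var),
    permanova_f = pmv$pseudo_f,
    permanova_p = pmv$p_value,
    classifier_auroc = auc
  )
}
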