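#' Multiple-testing adjustment with the missing-p convention
#'
#' Missing p-values (features dropped by a method's internal filtering) are
#' set to 1 before adjustment, then Benjamini-Hochberg or the more
#' conservative Benjamini-Yekutieli step-up is applied via `p.adjust`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values, same length.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  p[is.na(p)] <- 1
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Observed FDR and recall against a ground truth
#'
#' Discoveries are features with adjusted p strictly below `alpha`. The
#' observed FDR is the fraction of discoveries not in the truth set (defined
#' as 0 when nothing is discovered: a method that discovers nothing makes no
#' false discoveries); recall is the fraction of the truth set discovered.
#'
#' @param p_adj named (by feature id) adjusted p-values, or unnamed with
#'   `feature_ids` supplied.
#' @param truth character vector of ground-truth feature ids (non-empty).
#' @param alpha discovery cutoff (default 0.05).
#' @param feature_ids feature ids if `p_adj` is unnamed.
#' @return one-row tibble: `n_discoveries`, `observed_fdr`, `recall`.
#' @export
fdr_recall <- function(p_adj, truth, alpha = 0.05, feature_ids = names(p_adj)) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(feature_ids)) stop("feature ids required (name `p_adj` or pass `feature_ids`)", call. = FALSE)
  if (length(truth) == 0) stop("recall undefined for an empty ground truth", call. = FALSE)
  disc <- feature_ids[p_adj < alpha]
  fdr <- if (length(disc) == 0) 0 else length(setdiff(disc, truth)) / length(disc)
  tibble::tibble(
    n_discoveries = length(disc),
    observed_fdr = fdr,
    recall = length(intersect(disc, truth)) / length(truth)
  )
}

#' AUROC of raw p-values as a ground-truth predictor
#'
#' Probability that a random ground-truth feature receives a smaller raw p
#' than a random background feature, with ties counting one half (the
#' normalized Mann-Whitney U).
#'
#' @inheritParams fdr_recall
#' @param p_raw named raw p-values (or pass `feature_ids`).
#' @return a single AUROC in `[0, 1]`.
#' @export
auroc_from_pvalues <- function(p_raw, truth, feature_ids = names(p_raw)) {
  if (is.null(feature_ids)) stop("feature ids required", call. = FALSE)
  pos <- feature_ids %in% truth
  if (!any(pos) || all(pos)) stop("AUROC needs non-empty truth and background", call. = FALSE)
  rank_auroc(-p_raw, pos)
}

#' Flag whether a method's FDR control is sufficient across settings
#'
#' A method is flagged `"insufficient"` when its mean observed FDR exceeds
#' `fdr_limit` in more than `setting_limit` of the test settings
#' (combinations of effect and sample size), `"sufficient"` otherwise.
#'
#' @param mean_fdr vector of per-setting mean observed FDR values.
#' @param fdr_limit per-setting FDR threshold (default 0.10).
#' @param setting_limit tolerated fraction of exceeding settings (default 0.10).
#' @return `"sufficient"` or `"insufficient"`.
#' @export
fdr_control_flag <- function(mean_fdr, fdr_limit = 0.10, setting_limit = 0.10) {
  stopifnot(length(mean_fdr) >= 1)
  frac <- mean(mean_fdr > fdr_limit)
  if (frac > setting_limit) "insufficient" else "sufficient"
}

#' Classify a feature's disease/drug robustness from four models
#'
#' Reproduces the four-model classification used for drug-confounding
#' analysis: given BH-adjusted significance of the disease and drug terms in
#' naive and adjusted models, each feature is assigned exactly one category.
#'
#' @param p_naive_disease,p_naive_drug,p_adj_disease,p_adj_drug adjusted
#'   p-values (vectors recycle to a common length).
#' @param fdr significance cutoff (default 0.05).
#' @return character vector of categories: `"drug-and-disease"`,
#'   `"disease-associated"`, `"drug-confounded"`, `"drug-associated"` or
#'   `"none"`.
#' @export
classify_feature_robustness <- function(p_naive_disease, p_naive_drug,
                                        p_adj_disease, p_adj_drug, fdr = 0.05) {
  n <- max(lengths(list(p_naive_disease, p_naive_drug, p_adj_disease, p_adj_drug)))
  nd <- rep_len(p_naive_disease, n) < fdr
  ng <- rep_len(p_naive_drug, n) < fdr
  ad <- rep_len(p_adj_disease, n) < fdr
  ag <- rep_len(p_adj_drug, n) < fdr
  dplyr::case_when(
    nd & ng & ad & ag ~ "drug-and-disease",
    nd & ad & !ag ~ "disease-associated",
    nd & ng & !ad ~ "drug-confounded",
    !nd & !ad & ng & ag ~ "drug-associated",
    .default = "none"
  )
}

#' Evaluate one DA result against a ground truth
#'
#' Applies the adjustment (BH by default; score-based results such as the
#' ANCOM W score bypass adjustment and use the raw score at the cutoff),
#' then computes observed FDR, recall and AUROC.
#'
#' @param result a DA result tibble from [run_da_test()].
#' @param truth character vector of ground-truth feature ids.
#' @param alpha discovery cutoff (default 0.05).
#' @param adjust `"BH"` or `"BY"`.
#' @return one-row tibble: `method`, `n_discoveries`, `observed_fdr`,
#'   `recall`, `auroc`.
#' @export
evaluate_result <- function(result, truth, alpha = 0.05, adjust = "BH") {
  stopifnot(is.data.frame(result), all(c("feature_id", "p_raw", "is_score") %in% names(result)))
  p_adj <- if (any(result$is_score)) result$p_raw else adjust_pvalues(result$p_raw, adjust)
  fr <- fdr_recall(p_adj, truth, alpha = alpha, feature_ids = result$feature_id)
  auc <- auroc_from_pvalues(result$p_raw, truth, feature_ids = result$feature_id)
  tibble::tibble(method = result$method[1], fr, auroc = auc)
}
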