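# brute-force BH step-up: sort, scale, cumulative minimum from the largest p
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

test_that("BH/BY adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.37), 0.37)

  for (s in 1:10) {
    p <- withr::with_seed(s, runif(sample(c(5, 50, 1000), 1)))
    expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p))
    expect_true(all(adjust_pvalues(p, "BY") >= adjust_pvalues(p, "BH")))
  }
  # missing p-values are imputed to 1 before adjustment
  expect_equal(adjust_pvalues(c(0.5, NA)), bh_oracle(c(0.5, 1)))
  expect_error(adjust_pvalues(c(0.5, 2)), "outside")
})

test_that("p-value AUROC equals exhaustive pair counting", {
  pair_auroc <- function(p, pos) {
    pairs <- expand.grid(i = which(pos), j = which(!pos))
    mean(ifelse(p[pairs$i] < p[pairs$j], 1, ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  }
  p <- c(a = 0.01, b = 0.2, c = 0.05, d = 0.5)
  expect_equal(auroc_from_pvalues(p, c("a", "b")), 0.75)

  for (s in 1:10) {
    n <- 30
    p <- withr::with_seed(s, round(runif(n), 2)) # ties on purpose
    names(p) <- sprintf("f%02d", 1:n)
    truth <- names(p)[1:8]
    expect_equal(
      auroc_from_pvalues(p, truth),
      pair_auroc(p, names(p) %in% truth)
    )
  }
  expect_equal(auroc_from_pvalues(setNames(rep(0.2, 10), letters[1:10]), c("a", "b")), 0.5)
  expect_error(auroc_from_pvalues(setNames(0.1, "a"), "a"), "non-empty")
})

test_that("observed FDR and recall follow the discovery conventions", {
  p <- c(A = 0.01, B = 0.2, C = 0.03, D = 0.8)
  r <- fdr_recall(p, truth = c("A", "B"))
  expect_equal(r$observed_fdr, 0.5) # discoveries {A, C}
  expect_equal(r$recall, 0.5)

  none <- fdr_recall(c(A = 0.9, B = 0.8), truth = "A")
  expect_equal(none$observed_fdr, 0)
  expect_equal(none$recall, 0)

  exact <- fdr_recall(c(A = 0.01, B = 0.01, C = 0.9), truth = c("A", "B"))
  expect_equal(exact$observed_fdr, 0)
  expect_equal(exact$recall, 1)

  # strict inequality at the cutoff
  expect_equal(fdr_recall(c(A = 0.05), truth = "A")$n_discoveries, 0)
  expect_error(fdr_recall(p, truth = character()), "empty ground truth")

  # invariance to feature order
  perm <- c("D", "B", "A", "C")
  expect_equal(fdr_recall(p[perm], truth = c("A", "B")), r)
})

test_that("the FDR sufficiency rule flags the right fraction of settings", {
  expect_equal(fdr_control_flag(c(rep(0.02, 26), 0.2, 0.3)), "sufficient") # 2/28
  expect_equal(fdr_control_flag(c(rep(0.02, 24), rep(0.2, 4))), "insufficient") # 4/28
  expect_equal(fdr_control_flag(rep(0.08, 10)), "sufficient")
})

test_that("four-model robustness classification covers its cases", {
  s <- 0.01
  n <- 0.5
  expect_equal(classify_feature_robustness(s, s, s, s), "drug-and-disease")
  expect_equal(classify_feature_robustness(s, n, s, n), "disease-associated")
  expect_equal(classify_feature_robustness(s, s, s, n), "disease-associated")
  expect_equal(classify_feature_robustness(s, s, n, s), "drug-confounded")
  expect_equal(classify_feature_robustness(n, s, n, s), "drug-associated")
  expect_equal(classify_feature_robustness(n, n, n, n), "none")
  expect_equal(
    classify_feature_robustness(c(s, n), c(s, n), c(s, n), c(s, n)),
    c("drug-and-disease", "none")
  )
})

test_that("score-based results bypass adjustment in evaluate_result", {
  res <- tibble::tibble(
    method = "ancomw", transform = "none",
    feature_id = c("A", "B", "C", "D"),
    statistic = c(30, 2, 1, 0), p_raw = c(0.01, 0.6, 0.8, 0.9),
    is_score = TRUE, covariate_used = FALSE
  )
  ev <- evaluate_result(res, truth = "A")
  expect_equal(ev$n_discoveries, 1) # raw score < 0.05, no BH
  expect_equal(ev$recall, 1)
})
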