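g10 <- rep(c("1", "2"), each = 10)

mat1 <- function(v, ids = "f1") {
  matrix(v, 1, length(v), dimnames = list(ids, sprintf("s%02d", seq_along(v))))
}

test_that("wilcoxon: ties give p = 1, complete separation gives the exact p", {
  expect_equal(da_wilcoxon(mat1(rep(2, 20)), g10)$p_raw, 1)
  # 10 vs 10 fully separated distinct values: exact two-sided p = 2/choose(20,10)
  sep <- mat1(c(1:10, 101:110))
  expect_equal(da_wilcoxon(sep, g10)$p_raw, 2 / 184756)
})

test_that("blocked wilcoxon reduces to the naive test for one stratum and resists strata", {
  withr::with_seed(2, m <- mat1(runif(20)))
  naive <- run_da_test(matrix(1L, 1, 20, dimnames = dimnames(m)), g10, "wilcoxon")
  one_stratum <- da_wilcoxon(m, g10, block = rep("x", 20))
  expect_equal(one_stratum$p_raw, da_wilcoxon(m, g10)$p_raw)

  # a strong stratum effect aligned with the label: blocked p is larger
  strat <- rep(c("a", "b"), c(12, 8))
  v <- ifelse(strat == "a", 10, 0) + withr::with_seed(3, rnorm(20, sd = 0.1))
  gl <- rep("1", 20)
  gl[c(1:7, 13:15)] <- "2" # label correlated with stratum
  p_naive <- da_wilcoxon(mat1(v), gl)$p_raw
  p_block <- da_wilcoxon(mat1(v), gl, block = strat)$p_raw
  expect_gt(p_block, p_naive)

  # strata with an empty group are dropped with a warning
  bad <- c(rep("a", 10), rep("b", 10))
  gl2 <- c(rep("1", 10), rep(c("1", "2"), 5))
  expect_warning(da_wilcoxon(mat1(v), gl2, block = bad), "dropping stratum")
})

test_that("welch t-test matches its closed form and handles degenerate variance", {
  m <- mat1(c(1:5, 3:7))
  g5 <- rep(c("1", "2"), each = 5)
  res <- da_ttest(m, g5)
  # equal variances 2.5 -> t = -2 on Welch-Satterthwaite df = 8
  expect_equal(unname(res$statistic), -2)
  expect_equal(res$p_raw, 2 * pt(-2, 8))
  expect_equal(res$p_raw, t.test(1:5, 3:7)$p.value) # base-R route agrees

  expect_equal(da_ttest(mat1(rep(3, 10)), g5)$p_raw, 1)
  expect_equal(da_ttest(mat1(rep(c(0, 1), each = 5)), g5)$p_raw, 1)
})

test_that("KS statistic equals the ECDF supremum", {
  m <- mat1(c(1, 2, 3, 1.5, 2.5, 3.5))
  g3 <- rep(c("1", "2"), each = 3)
  res <- da_ks(m, g3)
  expect_equal(unname(res$statistic), 1 / 3)
  expect_equal(da_ks(mat1(rep(c(1, 2, 3), 2)), g3)$statistic[[1]], 0)
  expect_equal(da_ks(mat1(rep(c(1, 2, 3), 2)), g3)$p_raw, 1)
  expect_equal(da_ks(mat1(c(1, 2, 3, 11, 12, 13)), g3)$statistic[[1]], 1)
})

test_that("naive LM equals the pooled t-test (F = t^2) and adjusted variants behave", {
  withr::with_seed(5, m <- mat1(rnorm(20)))
  p_lm <- da_lm(m, g10)$p_raw
  p_pooled <- t.test(m[1, 1:10], m[1, 11:20], var.equal = TRUE)$p.value
  expect_equal(p_lm, p_pooled)

  # single-level covariate degenerates to the naive model
  p_deg <- da_lm(m, g10, covariate = rep("z", 20), covariate_role = "random")$p_raw
  expect_equal(p_deg, p_lm, tolerance = 1e-6)

  # orthogonal design: fixed-adjusted label p ~ naive p on residualized data
  z <- rep(c("a", "b"), 10) # orthogonal to g10
  withr::with_seed(6, v <- rnorm(20) + ifelse(z == "a", 5, 0) + ifelse(g10 == "2", 1, 0))
  p_fix <- da_lm(mat1(v), g10, covariate = z, covariate_role = "fixed")$p_raw
  resid_v <- residuals(lm(v ~ z))
  p_resid <- da_lm(mat1(resid_v), g10)$p_raw
  expect_equal(p_fix, p_resid, tolerance = 0.05)
  expect_lt(p_fix, 0.05) # the label effect is recovered despite the covariate

  # random-intercept model: detects the label, absorbs the stratum
  p_mix <- da_lm(mat1(v), g10, covariate = z, covariate_role = "random")$p_raw
  expect_lt(p_mix, 0.05)
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  withr::with_seed(8, {
    sds <- sqrt(rchisq(300, 4) / 4)
    m <- matrix(rnorm(300 * 20, sd = rep(sds, 20)), 300, 20,
      dimnames = list(sprintf("f%03d", 1:300), sprintf("s%02d", 1:20))
    )
    m[1:20, 11:20] <- m[1:20, 11:20] + 2
  })
  mine <- da_moderated_t(m, g10)
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, as.integer(g10 == "2"))))
  expect_equal(mine$p_raw, unname(fit$p.value[, 2]), tolerance = 0.005)
  expect_equal(unname(mine$statistic), unname(fit$t[, 2]), tolerance = 0.01)
})

test_that("variance shrinkage limits: no spread -> full pooling; d0 = 0 -> no pooling", {
  # zero spread in the observed variances -> infinite prior df, full pooling
  # (the prior includes the chi-square bias correction exp(log df/2 - digamma(df/2)))
  sq_equal <- mimicbench:::squeeze_variances(rep(2, 50), df = 10)
  expect_true(is.infinite(sq_equal$d0))
  expect_equal(sq_equal$s2_shrunk, rep(sq_equal$s0sq, 50))
  expect_equal(sq_equal$s0sq, 2, tolerance = 0.15)

  # genuine spread in the underlying variances (scaled inverse chi-square,
  # d0 = 4) -> a finite prior df in a plausible range
  withr::with_seed(9, {
    sigma2 <- 4 / rchisq(500, 4)
    s2 <- sigma2 * rchisq(500, 5) / 5
  })
  sq <- mimicbench:::squeeze_variances(s2, df = 5)
  expect_true(sq$d0 > 1 && sq$d0 < 20)
  # shrunk variances lie between the observed value and the prior
  between <- (sq$s2_shrunk - s2) * (sq$s2_shrunk - sq$s0sq) <= 1e-12
  expect_true(all(between))
})

test_that("moderated p-values are uniform under the Gaussian null", {
  withr::with_seed(10, m <- matrix(rnorm(1000 * 20), 1000, 20,
    dimnames = list(sprintf("f%04d", 1:1000), sprintf("s%02d", 1:20))
  ))
  res <- da_moderated_t(m, g10)
  expect_gt(ks.test(res$p_raw, "punif")$p.value, 0.01)
})

test_that("ANCOM W scores order features correctly", {
  cm <- toy_cm(40, 30, seed = 12) + 1L # avoid all-zero ratios
  g <- rep(c("1", "2"), each = 15)
  # inject one hugely scaled feature
  cm[5, 16:30] <- cm[5, 16:30] * 100L
  res <- da_ancom_w(cm, g)
  expect_gte(res$statistic[5], 0.9 * (nrow(cm) - 1))
  expect_lt(res$p_raw[5], 0.05)

  # the score map is strictly decreasing in W
  o <- order(res$statistic)
  expect_true(all(diff(res$p_raw[o]) <= 0))
  w_range <- tibble::tibble(w = res$statistic, s = res$p_raw) |> dplyr::distinct()
  expect_true(all(w_range$s > 0 & w_range$s <= 1))

  # null data: W concentrates near 0, scores near 1
  null_res <- da_ancom_w(toy_cm(30, 30, seed = 13) + 1L, g)
  expect_gt(median(null_res$p_raw), 0.8)
  expect_error(da_ancom_w(cm[1:2, ], g), "at least 3")
})

test_that("all tests are invariant to joint sample/label permutation", {
  cm <- filtered_baseline()[, 1:40]
  g <- rep(c("1", "2"), 20)
  perm <- withr::with_seed(14, sample(40))
  for (m in c("wilcoxon", "ttest", "ks", "lm", "modt")) {
    a <- run_da_test(cm, g, m)
    b <- run_da_test(cm[, perm], g[perm], m)
    expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12, info = m)
  }
})

test_that("the dispatcher applies the documented default transforms", {
  cm <- filtered_baseline()[, 1:30]
  g <- rep(c("1", "2"), 15)
  expect_equal(run_da_test(cm, g, "wilcoxon")$transform[1], "TSS")
  expect_equal(run_da_test(cm, g, "modt")$transform[1], "TSS.log")
  expect_equal(run_da_test(cm, g, "ancomw")$transform[1], "none")
  expect_error(run_da_test(cm, g, "lmm"), "confounder")
})
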