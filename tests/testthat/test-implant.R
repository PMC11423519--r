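test_that("group splits are balanced, deterministic, and refuse tiny inputs", {
  cm <- toy_cm(5, 100)
  g <- split_groups(cm, seed = 1)
  expect_equal(as.vector(table(g)), c(50, 50))
  expect_identical(g, split_groups(cm, seed = 1))
  expect_false(identical(g, split_groups(cm, seed = 2)))

  odd <- toy_cm(5, 101)
  expect_equal(sort(as.vector(table(split_groups(odd, seed = 3)))), c(50, 51))
  expect_error(split_groups(toy_cm(5, 3), seed = 1), "at least 4")
})

test_that("feature selection sizes and eligibility rules hold", {
  cm <- generate_baseline(baseline_spec(300, 60, seed = 2))
  expect_length(select_da_features(cm, 0.1, seed = 1), 30)
  expect_length(select_da_features(cm, 0, seed = 1), 0)

  # a feature non-zero in 30% of samples has q75 > 0 and is never "low"
  cm2 <- toy_cm(10, 20, seed = 5)
  cm2["feat_01", ] <- 0L
  cm2["feat_01", 1:6] <- 3L # prevalence 0.3 -> q75 > 0
  cm2["feat_02", ] <- 0L
  cm2["feat_02", 1:2] <- 2L # prevalence 0.1 -> q75 = 0
  for (s in 1:10) {
    sel <- select_da_features(cm2, 0.1, mode = "low", seed = s)
    expect_false("feat_01" %in% sel)
  }
  expect_error(
    select_da_features(cm2, 0.9, mode = "low", seed = 1),
    "eligible pool"
  )
})

test_that("prevalence shift swaps the requested entries and conserves zeros", {
  # feature with 10 non-zeros in donor group 1, 5 zeros in target group 2
  cm <- matrix(0L, 2, 30, dimnames = list(c("fa", "fb"), sprintf("s%02d", 1:30)))
  g <- rep(c("1", "2"), each = 15)
  cm["fa", 1:10] <- 7L # donor non-zeros
  cm["fa", 16:25] <- 4L # target: 10 non-zero, 5 zero
  cm["fb", ] <- 1L
  out <- implant_prevalence(cm, g, "fa", shift = 0.2, direction = c(fa = 2L), seed = 9)
  # k = round(0.2 * 10) = 2 swaps; zero totals conserved
  expect_equal(sum(out["fa", ] == 0), sum(cm["fa", ] == 0))
  expect_equal(sum(out["fa", 16:30] == 0), 3) # target gained 2 non-zeros
  expect_equal(sum(out["fa", 1:15] > 0), 8) # donor lost 2
  expect_equal(sort(as.vector(out["fa", ])), sort(as.vector(cm["fa", ]))) # values only move

  # no zeros available in the target group: no swaps, no error
  cm2 <- cm
  cm2["fa", 16:30] <- 2L
  out2 <- implant_prevalence(cm2, g, "fa", shift = 0.5, direction = c(fa = 2L), seed = 1)
  expect_identical(out2, cm2)

  # shift 0 is the identity
  expect_identical(implant_prevalence(cm, g, "fa", 0, direction = c(fa = 2L)), cm)
})

test_that("abundance scaling multiplies non-zeros, preserves the zero pattern", {
  cm <- toy_cm(8, 20, seed = 4)
  g <- rep(c("1", "2"), each = 10)
  feats <- c("feat_02", "feat_05")
  dir <- c(feat_02 = 2L, feat_05 = 1L)
  out <- implant_abundance(cm, g, feats, scale = 2, direction = dir)
  expect_identical(out == 0, cm == 0) # zero pattern untouched
  tgt <- 11:20
  expect_equal(out["feat_02", tgt], cm["feat_02", tgt] * 2L)
  expect_identical(out["feat_02", 1:10], cm["feat_02", 1:10])
  untouched <- setdiff(rownames(cm), feats)
  expect_identical(out[untouched, ], cm[untouched, ])

  # scale 1 is the identity; count 1 at scale 1.25 stays 1 (floor rule)
  expect_identical(implant_abundance(cm, g, feats, 1, direction = dir), cm)
  cm1 <- cm
  cm1["feat_02", 11] <- 1L
  out1 <- implant_abundance(cm1, g, "feat_02", 1.25, direction = c(feat_02 = 2L))
  expect_identical(out1["feat_02", 11], 1L)
  # 7 * 2 = 14 under round-half-up
  cm7 <- cm
  cm7["feat_02", 12] <- 7L
  expect_identical(
    implant_abundance(cm7, g, "feat_02", 2, direction = c(feat_02 = 2L))["feat_02", 12],
    14L
  )
})

test_that("implant_signal alternates target groups and is deterministic", {
  cm <- filtered_baseline()
  ds <- implant_signal(cm, seed = 21, scale = 5, shift = 0.2)
  tab <- table(ds$truth$target_group)
  expect_lte(abs(tab[["1"]] - tab[["2"]]), 1)
  ds2 <- implant_signal(cm, seed = 21, scale = 5, shift = 0.2)
  expect_identical(ds$counts, ds2$counts)
  expect_equal(ds$truth, ds2$truth)
})

test_that("the null grid point returns the input untouched with all features rejected", {
  cm <- filtered_baseline()
  ds <- implant_signal(cm, seed = 8, scale = 1, shift = 0)
  expect_identical(ds$counts, cm)
  expect_true(all(ds$truth$rejected))
  expect_length(truth_features(ds), 0)
})

test_that("strong effects survive gFC rejection and |gFC| grows with effect size", {
  cm <- filtered_baseline()
  ds_big <- implant_signal(cm, seed = 13, scale = 20, shift = 0.3)
  expect_true(all(abs(ds_big$truth$gfc[!ds_big$truth$rejected]) >= 0.001))
  expect_gt(sum(!ds_big$truth$rejected), 0)

  mean_gfc <- function(scale, shift) {
    ds <- implant_signal(cm, seed = 13, scale = scale, shift = shift)
    mean(abs(ds$truth$gfc))
  }
  expect_lte(mean_gfc(1.25, 0), mean_gfc(2, 0))
  expect_lte(mean_gfc(2, 0), mean_gfc(10, 0))
  expect_lte(mean_gfc(2, 0), mean_gfc(2, 0.3))
})

test_that("implanted direction matches the sign of the realized gFC", {
  cm <- filtered_baseline()
  ds <- implant_signal(cm, seed = 31, scale = 10, shift = 0.2)
  kept <- dplyr::filter(ds$truth, !rejected, abs(gfc) > 0.05)
  expect_true(all(sign(kept$gfc) == ifelse(kept$target_group == 2, 1, -1)))
})

test_that("compositional implantation conserves library sizes and depletes background", {
  cm <- filtered_baseline()
  before <- colSums(cm)
  ds <- implant_compositional(cm, seed = 17, scale = 10, shift = 0, fraction = 0.1)
  expect_true(all(colSums(ds$counts) <= before))
  # every inflated sample was rarefied back to its original total
  expect_true(all(colSums(ds$counts)[ds$labels == "2"] == before[ds$labels == "2"]))

  bg <- setdiff(rownames(cm), ds$truth$feature_id)
  relab <- sweep(ds$counts, 2, colSums(ds$counts), "/")
  bg_g1 <- mean(relab[bg, ds$labels == "1"])
  bg_g2 <- mean(relab[bg, ds$labels == "2"])
  expect_lt(bg_g2, bg_g1) # spurious depletion in the implanted group

  # null point: no modification, no rarefaction
  ds0 <- implant_compositional(cm, seed = 17, scale = 1, shift = 0)
  expect_identical(ds0$counts, cm)
})
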