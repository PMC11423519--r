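test_that("config enumeration length equals the analytic product", {
  expect_equal(nrow(enumerate_configs(benchmark_grid())), 980000)

  small <- benchmark_grid(
    abundance_scales = c(1, 2), prev_shifts = c(0, 0.2),
    n_implant_repeats = 2, sample_sizes = c(12, 24), n_subsamples = 2
  )
  expect_equal(nrow(enumerate_configs(small)), 32)
  single <- benchmark_grid(1, 0, 1, 12, 1)
  expect_equal(nrow(enumerate_configs(single)), 1)

  for (s in 1:5) {
    dims <- withr::with_seed(s, sample(1:4, 5, replace = TRUE))
    g <- benchmark_grid(
      abundance_scales = seq(1, 2, length.out = dims[1]),
      prev_shifts = seq(0, 0.3, length.out = dims[2]),
      n_implant_repeats = dims[3],
      sample_sizes = seq_len(dims[4]) * 2,
      n_subsamples = dims[5]
    )
    expect_equal(nrow(enumerate_configs(g)), prod(dims))
  }
})

test_that("test indices draw n/2 per group, without duplicates, deterministically", {
  labels <- factor(rep(c("1", "2"), each = 60))
  idx <- generate_test_indices(labels, sizes = c(12, 100), n_subsamples = 5, seed = 3)
  expect_equal(nrow(idx), 5 * (12 + 100))
  one <- dplyr::filter(idx, sample_size == 100, subsample == 2)
  expect_equal(sum(labels[one$position] == "1"), 50)
  expect_equal(sum(labels[one$position] == "2"), 50)
  expect_false(anyDuplicated(one$position) > 0)
  expect_true(all(idx$position %in% seq_along(labels)))

  idx2 <- generate_test_indices(labels, sizes = c(12, 100), n_subsamples = 5, seed = 3)
  expect_equal(idx, idx2)
  expect_error(generate_test_indices(labels, sizes = 200, n_subsamples = 1), "availability")
})

test_that("child seeds are deterministic, path-sensitive and within integer range", {
  expect_identical(child_seed(1, 2, 3), child_seed(1, 2, 3))
  expect_false(child_seed(1, 2, 3) == child_seed(1, 3, 2))
  seeds <- vapply(1:500, function(k) child_seed(42, k), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31 - 1))
  expect_gt(length(unique(seeds)), 495) # collisions essentially absent
})

test_that("a small benchmark sweep is reproducible and resumes from a store", {
  cm <- filtered_baseline()
  grid <- benchmark_grid(
    abundance_scales = c(1, 5), prev_shifts = 0,
    n_implant_repeats = 2, sample_sizes = 24, n_subsamples = 2,
    master_seed = 11
  )
  r1 <- run_benchmark(cm, grid, methods = c("wilcoxon", "ttest"))
  r2 <- run_benchmark(cm, grid, methods = c("wilcoxon", "ttest"))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2 * 2 * 2 * 2)
  expect_true(all(r1$observed_fdr >= 0 & r1$observed_fdr <= 1, na.rm = TRUE))
  # null grid point: recall undefined, FDR is the any-false-discovery indicator
  expect_true(all(is.na(r1$recall[r1$abundance_scale == 1])))

  # store round: resume gives identical results without recomputation drift
  store <- sim_store(withr::local_tempdir())
  s1 <- run_benchmark(cm, grid, methods = "wilcoxon", store = store)
  expect_equal(sort(store_keys(store)), sort(unique(sprintf(
    "ab%g_prev0_rep%03d", rep(c(1, 5), each = 2), 1:2
  ))))
  s2 <- run_benchmark(cm, grid, methods = "wilcoxon", store = store)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(
    as.data.frame(dplyr::select(s1, -dplyr::any_of("n_discoveries"))),
    as.data.frame(dplyr::select(
      dplyr::filter(r1, method == "wilcoxon"),
      -dplyr::any_of("n_discoveries")
    ))
  )
})

test_that("summaries aggregate per setting and carry the sufficiency flag", {
  cm <- filtered_baseline()
  grid <- benchmark_grid(
    abundance_scales = c(1, 5), prev_shifts = 0,
    n_implant_repeats = 2, sample_sizes = 24, n_subsamples = 2,
    master_seed = 11
  )
  res <- run_benchmark(cm, grid, methods = "wilcoxon")
  smry <- summarize_benchmark(res)
  expect_equal(nrow(smry), 2) # two settings
  expect_true(all(smry$fdr_control %in% c("sufficient", "insufficient")))
  expect_equal(smry$n_runs, c(4, 4))
  p <- autoplot(smry)
  expect_s3_class(p, "ggplot")
})
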