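# Shared fixtures, all generated in code.

# small deterministic integer matrix with ids
toy_cm <- function(n_features = 6, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_features * n_samples, 5), n_features, n_samples)
    m[withr::with_seed(seed + 1, sample(length(m), length(m) %/% 3))] <- 0L
  })
  storage.mode(m) <- "integer"
  dimnames(m) <- list(
    sprintf("feat_%02d", seq_len(n_features)),
    sprintf("samp_%02d", seq_len(n_samples))
  )
  m
}

# medium filtered synthetic baseline, cached per session
filtered_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- filter_features(
        generate_baseline(baseline_spec(n_features = 120, n_samples = 120, seed = 42))
      )
    }
    cache
  }
})

expect_same_matrix <- function(a, b) {
  expect_identical(dim(a), dim(b))
  expect_identical(dimnames(a), dimnames(b))
  expect_equal(unname(a), unname(b))
}
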