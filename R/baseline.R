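#' Specification for a synthetic baseline count table
#'
#' Parameters of the built-in generator that emulates the salient properties
#' of real stool shotgun-metagenomic taxonomic profiles: high per-sample
#' sparsity, heavy-tailed feature abundances, mean-variance overdispersion and
#' lognormal library-size variation. The generator exists so the whole
#' benchmarking workflow can run offline; it makes no claim of statistical
#' indistinguishability from any real cohort.
#'
#' @param n_features number of taxa (default 300).
#' @param n_samples number of samples (default 200).
#' @param depth_log_mean,depth_log_sd meanlog / sdlog of the lognormal
#'   library-size model (defaults give median depth 2e4).
#' @param feature_log_mean_sd spread (sd, log10 units) of per-feature mean
#'   log-abundances; larger values give heavier tails (default 1.5).
#' @param sample_log_sd sd of the per-sample log10 noise added to feature
#'   means before the softmax composition (default 0.6).
#' @param dispersion negative-binomial size parameter; smaller values give
#'   stronger overdispersion (default 0.3).
#' @param zero_inflation probability scale of extra zero-masking, applied
#'   preferentially to low-abundance features (default 0.3).
#' @param seed integer seed.
#' @return a `baseline_spec` list.
#' @export
baseline_spec <- function(n_features = 300, n_samples = 200,
                          depth_log_mean = log(2e4), depth_log_sd = 0.5,
                          feature_log_mean_sd = 1.5, sample_log_sd = 0.6,
                          dispersion = 0.3, zero_inflation = 0.3, seed = 1L) {
  stopifnot(
    n_features >= 1, n_samples >= 1, depth_log_sd >= 0,
    feature_log_mean_sd >= 0, sample_log_sd >= 0, dispersion > 0,
    zero_inflation >= 0, zero_inflation <= 1
  )
  structure(as.list(environment()), class = "baseline_spec")
}

#' Generate a synthetic baseline count table
#'
#' Draws per-feature log10 mean abundances from a normal with sd
#' `feature_log_mean_sd`, forms per-sample compositions by softmax of those
#' means plus per-sample noise, samples counts from a negative binomial at a
#' lognormal library depth, then masks additional zeros with a probability
#' that decays with feature abundance. Identical specs (including seed) give
#' identical matrices.
#'
#' @param spec a [baseline_spec()].
#' @return integer count matrix (features x samples) with ids `feat_###` /
#'   `samp_###`.
#' @export
#' @examples
#' cm <- generate_baseline(baseline_spec(n_features = 50, n_samples = 30, seed = 7))
#' mean(cm == 0) # sample sparsity
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  p <- spec
  withr::with_seed(p$seed, {
    mu <- stats::rnorm(p$n_features, mean = 0, sd = p$feature_log_mean_sd)
    depth <- pmax(1, round(stats::rlnorm(p$n_samples, p$depth_log_mean, p$depth_log_sd)))
    noise <- matrix(
      stats::rnorm(p$n_features * p$n_samples, 0, p$sample_log_sd),
      p$n_features, p$n_samples
    )
    loga <- mu + noise
    comp <- apply(loga, 2, function(v) {
      w <- 10^(v - max(v))
      w / sum(w)
    })
    mu_counts <- sweep(comp, 2, depth, "*")
    counts <- matrix(
      stats::rnbinom(length(mu_counts), size = p$dispersion, mu = mu_counts),
      p$n_features, p$n_samples
    )
    # extra zeros hit rare features hardest: p0 ~ zero_inflation * med/(m + med)
    m <- rowMeans(comp)
    p0 <- p$zero_inflation * stats::median(m) / (m + stats::median(m))
    mask <- matrix(
      stats::runif(length(counts)) < rep(p0, p$n_samples),
      p$n_features, p$n_samples
    )
    counts[mask] <- 0L
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(
    sprintf("feat_%03d", seq_len(p$n_features)),
    sprintf("samp_%03d", seq_len(p$n_samples))
  )
  counts
}
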