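#' Parametric comparison simulators
#'
#' Fits a simple parametric model to a baseline count table and simulates a
#' two-group dataset from it, as done in earlier DA benchmarking studies.
#' These generators exist as comparison points for the realism diagnostics —
#' they are the models whose output a classifier can tell apart from real
#' data, unlike implantation output.
#'
#' Families:
#' \describe{
#'   \item{multinomial}{samples drawn from the mean baseline composition;
#'     DA features are scaled after sampling (McMurdie-style).}
#'   \item{negative_binomial}{per-feature mean and dispersion estimated by
#'     method of moments (uncorrelated across features); DA feature means are
#'     scaled before sampling. Non-estimable dispersions (variance <= mean)
#'     are capped at a large finite size.}
#'   \item{dirichlet}{composition times `concentration` parameterises a
#'     Dirichlet; draws are multiplied by the sample depth and rounded to
#'     integers.}
#' }
#' Depths are resampled from the baseline's observed library sizes.
#'
#' @param cm filtered baseline count matrix.
#' @param family `"multinomial"`, `"negative_binomial"` or `"dirichlet"`.
#' @param effect_scale multiplier `>= 1` applied to the DA features
#'   (`1` = null simulation, empty ground truth).
#' @param n_samples_per_group samples per group (default: half the baseline).
#' @param fraction fraction of features made differentially abundant
#'   (default 0.1).
#' @param concentration Dirichlet concentration (default 100); larger values
#'   concentrate draws around the estimated composition.
#' @param max_size dispersion cap for the negative binomial (default 1e6).
#' @param seed integer seed.
#' @return a [sim_dataset()] with the scaled features as ground truth.
#' @export
simulate_parametric <- function(cm, family = c("multinomial", "negative_binomial", "dirichlet"),
                                effect_scale = 1,
                                n_samples_per_group = floor(ncol(cm) / 2),
                                fraction = 0.1, concentration = 100,
                                max_size = 1e6, seed = 1L) {
  assert_count_matrix(cm)
  family <- match.arg(family)
  stopifnot(effect_scale >= 1, n_samples_per_group >= 2)
  nf <- nrow(cm)
  n <- 2L * as.integer(n_samples_per_group)
  labels <- factor(rep(c("1", "2"), each = n_samples_per_group), levels = c("1", "2"))
  tss <- sweep(cm, 2, pmax(colSums(cm), 1), "/")
  comp <- rowMeans(tss)
  comp <- comp / sum(comp)
  da <- if (effect_scale > 1) {
    select_da_features(cm, fraction = fraction, seed = child_seed(seed, 2L))
  } else {
    character()
  }
  is_da <- rownames(cm) %in% da
  withr::with_seed(child_seed(seed, 1L), {
    depths <- sample(colSums(cm), n, replace = TRUE)
    counts <- switch(family,
      multinomial = {
        m <- vapply(depths, function(d) stats::rmultinom(1, d, comp)[, 1], numeric(nf))
        # post-hoc scaling in group 2, as in the multinomial benchmark designs
        if (any(is_da)) {
          g2 <- which(labels == "2")
          m[is_da, g2] <- round_half_up(m[is_da, g2, drop = FALSE] * effect_scale)
        }
        m
      },
      negative_binomial = {
        mu <- rowMeans(cm)
        v <- apply(cm, 1, stats::var)
        size <- ifelse(v > mu, mu^2 / (v - mu), max_size)
        size <- pmin(pmax(size, 1e-8), max_size)
        mean_depth <- mean(colSums(cm))
        m <- matrix(0, nf, n)
        for (j in seq_len(n)) {
          mu_j <- mu * depths[j] / mean_depth
          if (labels[j] == "2") mu_j[is_da] <- mu_j[is_da] * effect_scale
          m[, j] <- stats::rnbinom(nf, size = size, mu = mu_j)
        }
        m
      },
      dirichlet = {
        alpha <- comp * concentration
        m <- matrix(0, nf, n)
        for (j in seq_len(n)) {
          a <- alpha
          if (labels[j] == "2") a[is_da] <- a[is_da] * effect_scale
          x <- stats::rgamma(nf, shape = a, rate = 1)
          p <- if (sum(x) > 0) x / sum(x) else comp
          m[, j] <- round_half_up(p * depths[j])
        }
        m
      }
    )
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(rownames(cm), sprintf("psim_%03d", seq_len(n)))
  truth <- if (length(da)) {
    eff <- feature_effects(counts[da, , drop = FALSE], labels)
    tibble::tibble(
      feature_id = da, target_group = 2L, abundance_scale = effect_scale,
      prev_shift = 0, gfc = eff$gfc, prev_diff = eff$prev_diff, rejected = FALSE
    )
  } else {
    empty_ground_truth()
  }
  sim_dataset(counts, labels,
    truth = truth,
    params = list(
      seed = seed, family = family, effect_scale = effect_scale,
      fraction = fraction, concentration = concentration, type = "parametric"
    )
  )
}
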