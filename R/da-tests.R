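# Differential-abundance test battery. Every test consumes a (transformed)
# features x samples matrix plus two-level labels and returns a tibble with
# one row per feature under a uniform contract: features whose test cannot be
# computed (constant data, singular fits) carry p = 1, matching the
# missing-p convention used downstream.

da_tibble <- function(method, transform, feature_id, statistic, p_raw,
                      is_score = FALSE, covariate_used = FALSE) {
  p_raw <- unname(p_raw)
  p_raw[!is.finite(p_raw)] <- 1
  tibble::tibble(
    method = method, transform = transform, feature_id = feature_id,
    statistic = unname(statistic), p_raw = pmin(pmax(p_raw, 0), 1),
    is_score = is_score, covariate_used = covariate_used
  )
}

# tie-corrected normal-approximation rank-sum p (two-sided, continuity
# corrected); used by the stratified Wilcoxon and the ANCOM inner loop
ranksum_normal_p <- function(values, g2) {
  r <- rank(values)
  n <- length(values)
  n2 <- sum(g2)
  n1 <- n - n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  w <- sum(r[g2])
  mu <- n2 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)
  2 * stats::pnorm(-max(z, 0))
}

#' Wilcoxon rank-sum test per feature, optionally stratified
#'
#' Without `block`, the two-sided rank-sum test (base `wilcox.test`: exact
#' enumeration for small untied samples, otherwise normal approximation with
#' tie correction and continuity correction). With a `block` factor, a
#' van-Elteren-style stratified test: within-stratum rank-sum statistics are
#' combined over strata with tie-corrected variances, giving a test of the
#' label that conditions on the blocking (confounder) variable. Strata where
#' a group is empty are dropped with a warning; a single-stratum block
#' reduces to the naive test.
#'
#' @param mat numeric matrix (features x samples), typically TSS-normalized.
#' @param labels two-level group labels.
#' @param block optional stratification factor (e.g. the confounder).
#' @return a DA result tibble (`method`, `transform`, `feature_id`,
#'   `statistic`, `p_raw`, `is_score`, `covariate_used`).
#' @export
da_wilcoxon <- function(mat, labels, block = NULL) {
  g <- as_group_factor(labels, n = ncol(mat))
  if (!is.null(block)) {
    b <- factor(block)
    if (nlevels(b) > 1) {
      return(da_wilcoxon_blocked(mat, g, b))
    }
  }
  res <- apply(mat, 1, function(v) {
    if (length(unique(v)) == 1) return(c(0, 1))
    ht <- suppressWarnings(stats::wilcox.test(v[g == "1"], v[g == "2"]))
    c(ht$statistic, ht$p.value)
  })
  da_tibble("wilcoxon", NA_character_, rownames(mat), res[1, ], res[2, ])
}

da_wilcoxon_blocked <- function(mat, g, b) {
  keep <- levels(b)[vapply(levels(b), function(s) {
    length(unique(g[b == s])) == 2
  }, logical(1))]
  if (length(keep) < nlevels(b)) {
    warning("dropping stratum(s) with an empty group: ",
      paste(setdiff(levels(b), keep), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(keep) == 0) {
    return(da_tibble("wilcoxon-blocked", NA_character_, rownames(mat),
      rep(NA_real_, nrow(mat)), rep(1, nrow(mat)),
      covariate_used = TRUE
    ))
  }
  res <- apply(mat, 1, function(v) {
    num <- 0
    den <- 0
    for (s in keep) {
      i <- b == s
      vs <- v[i]
      gs <- g[i]
      n <- length(vs)
      n2 <- sum(gs == "2")
      n1 <- n - n2
      r <- rank(vs)
      w <- sum(r[gs == "2"])
      ties <- table(r)
      sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      num <- num + (w - n2 * (n + 1) / 2)
      den <- den + sig2
    }
    if (den <= 0) return(c(0, 1))
    z <- num / sqrt(den)
    c(z, 2 * stats::pnorm(-abs(z)))
  })
  da_tibble("wilcoxon-blocked", NA_character_, rownames(mat), res[1, ], res[2, ],
    covariate_used = TRUE
  )
}

#' Welch t-test per feature
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite df) via base
#' `t.test`. Features with zero variance in both groups get p = 1.
#'
#' @inheritParams da_wilcoxon
#' @return a DA result tibble.
#' @export
da_ttest <- function(mat, labels) {
  g <- as_group_factor(labels, n = ncol(mat))
  res <- apply(mat, 1, function(v) {
    out <- tryCatch(
      {
        ht <- stats::t.test(v[g == "1"], v[g == "2"])
        c(ht$statistic, ht$p.value)
      },
      error = function(e) c(0, 1)
    )
    out
  })
  da_tibble("ttest", NA_character_, rownames(mat), res[1, ], res[2, ])
}

#' Two-sample Kolmogorov-Smirnov test per feature
#'
#' Base `ks.test` with the asymptotic p-value (ties are pervasive in sparse
#' count data, so the exact computation is unavailable); the D statistic is
#' reported.
#'
#' @inheritParams da_wilcoxon
#' @return a DA result tibble.
#' @export
da_ks <- function(mat, labels) {
  g <- as_group_factor(labels, n = ncol(mat))
  res <- apply(mat, 1, function(v) {
    ht <- suppressWarnings(stats::ks.test(v[g == "1"], v[g == "2"], exact = FALSE))
    c(ht$statistic, ht$p.value)
  })
  da_tibble("ks", NA_character_, rownames(mat), res[1, ], res[2, ])
}

#' Linear-model test per feature, naive or confounder-adjusted
#'
#' Naive: per-feature ordinary least squares of the (transformed) abundance
#' on the binary label; the label's F-test p-value is extracted with
#' `anova`. With `covariate_role = "fixed"` the covariate enters as a fixed
#' effect and the label's partial t-test p is reported. With
#' `covariate_role = "random"` a random-intercept model
#' `feature ~ label + (1|covariate)` is fitted with `lmerTest` and the
#' label's Satterthwaite-df t-test p is reported; non-convergence falls back
#' to the fixed-effect model, and a single-level covariate degenerates to the
#' naive model.
#'
#' @inheritParams da_wilcoxon
#' @param covariate optional covariate (factor) for adjusted variants.
#' @param covariate_role `"none"`, `"fixed"` or `"random"`.
#' @return a DA result tibble.
#' @export
da_lm <- function(mat, labels, covariate = NULL,
                  covariate_role = c("none", "fixed", "random")) {
  g <- as_group_factor(labels, n = ncol(mat))
  covariate_role <- match.arg(covariate_role)
  if (covariate_role != "none") {
    if (is.null(covariate)) stop("covariate required for adjusted linear models", call. = FALSE)
    z <- factor(covariate)
    if (nlevels(z) < 2) covariate_role <- "none"
  }
  method <- switch(covariate_role, none = "lm", fixed = "lm-fixed", random = "lmm")
  fit_one <- switch(covariate_role,
    none = function(v) {
      fit <- stats::lm(v ~ g)
      a <- stats::anova(fit)
      c(a[1, "F value"], a[1, "Pr(>F)"])
    },
    fixed = function(v) {
      fit <- stats::lm(v ~ g + z)
      co <- summary(fit)$coefficients
      if (!"g2" %in% rownames(co)) return(c(0, 1))
      co["g2", c("t value", "Pr(>|t|)")]
    },
    random = function(v) {
      tryCatch(
        {
          m <- suppressMessages(suppressWarnings(
            lmerTest::lmer(v ~ g + (1 | z), REML = TRUE)
          ))
          co <- stats::coef(summary(m))
          c(co["g2", "t value"], co["g2", "Pr(>|t|)"])
        },
        error = function(e) {
          fit <- stats::lm(v ~ g + z)
          co <- summary(fit)$coefficients
          if (!"g2" %in% rownames(co)) return(c(0, 1))
          co["g2", c("t value", "Pr(>|t|)")]
        }
      )
    }
  )
  res <- apply(mat, 1, function(v) {
    if (stats::var(v) == 0) return(c(0, 1))
    out <- tryCatch(fit_one(v), error = function(e) c(0, 1))
    if (any(!is.finite(out))) c(0, 1) else out
  })
  da_tibble(method, NA_character_, rownames(mat), res[1, ], res[2, ],
    covariate_used = covariate_role != "none"
  )
}

# empirical-Bayes variance shrinkage: moment-matching of log residual
# variances; trigamma inversion by Newton iterations (tolerance 1e-8)
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    return(list(d0 = 0, s0sq = mean(s2), s2_shrunk = s2))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  target <- stats::var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    y <- 0.5 + 1 / target # starting value; trigamma(y) ~ 1/y for large y
    for (i in 1:50) {
      delta <- (trigamma(y) - target) / psigamma(y, 2)
      y <- y - delta
      if (y <= 0) y <- 1e-8
      if (abs(delta) < 1e-8 * y) break
    }
    d0 <- 2 * y
    s0sq <- exp(emean + digamma(y) - log(y))
  }
  s2_shrunk <- if (is.infinite(d0)) {
    rep(s0sq, length(s2))
  } else {
    (d0 * s0sq + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0sq = s0sq, s2_shrunk = s2_shrunk)
}

#' Moderated t-test per feature (empirical-Bayes variance shrinkage)
#'
#' Fits the per-feature two-group linear model, shrinks the residual
#' variances toward a common prior estimated by moment matching of the log
#' variances (the moderated t-statistic of empirical-Bayes linear modelling),
#' and tests the group coefficient on `d0 + df` degrees of freedom. With
#' fewer than 2 residual df the ordinary Welch t-test is used with a warning.
#'
#' @inheritParams da_wilcoxon
#' @return a DA result tibble.
#' @export
da_moderated_t <- function(mat, labels) {
  g <- as_group_factor(labels, n = ncol(mat))
  i1 <- g == "1"
  n1 <- sum(i1)
  n2 <- sum(!i1)
  df <- n1 + n2 - 2
  if (df < 2) {
    warning("fewer than 2 residual df; falling back to the ordinary t-test", call. = FALSE)
    out <- da_ttest(mat, labels)
    out$method <- "modt"
    return(out)
  }
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, !i1, drop = FALSE])
  ss <- rowSums((mat[, i1, drop = FALSE] - m1)^2) +
    rowSums((mat[, !i1, drop = FALSE] - m2)^2)
  s2 <- ss / df
  sq <- squeeze_variances(s2, df)
  vg <- 1 / n1 + 1 / n2
  tstat <- (m2 - m1) / sqrt(sq$s2_shrunk * vg)
  tstat[!is.finite(tstat)] <- 0
  df_total <- df + sq$d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else 2 * stats::pt(-abs(tstat), df_total)
  da_tibble("modt", NA_character_, rownames(mat), tstat, p)
}

#' ANCOM W statistic with a score transform
#'
#' For each feature, counts how many pairwise log-ratio tests against the
#' other features reject at `alpha_inner` (rank-sum test with normal
#' approximation). W values at or above the conventional decision threshold
#' `0.7 x (m - 1)` are mapped strictly decreasingly into (0, 0.05) — a
#' "discovery" — and all lower W strictly decreasingly into [0.05, 1]. The
#' scores are *not* p-values (`is_score = TRUE`) and must bypass
#' multiple-testing adjustment; discoveries are `score < 0.05` directly.
#'
#' @param counts count matrix (the test operates on `log(count + pseudocount)`
#'   ratios).
#' @param labels two-level group labels.
#' @param alpha_inner rejection level of the pairwise tests (default 0.05).
#' @param pseudocount added to counts before log (default 1).
#' @return a DA result tibble with `statistic` = W and `p_raw` = score.
#' @export
da_ancom_w <- function(counts, labels, alpha_inner = 0.05, pseudocount = 1) {
  g <- as_group_factor(labels, n = ncol(counts))
  m <- nrow(counts)
  if (m < 3) stop("ANCOM needs at least 3 features", call. = FALSE)
  l <- log(counts + pseudocount)
  g2 <- g == "2"
  w <- integer(m)
  for (i in seq_len(m - 1)) {
    di <- sweep(l[(i + 1):m, , drop = FALSE], 2, l[i, ], "-")
    p_ij <- apply(di, 1, ranksum_normal_p, g2 = g2)
    rej <- !is.na(p_ij) & p_ij < alpha_inner
    w[i] <- w[i] + sum(rej)
    w[(i + 1):m] <- w[(i + 1):m] + rej
  }
  thr <- 0.7 * (m - 1)
  score <- ifelse(
    w >= thr,
    0.05 * ((m - 1) - w + 0.5) / ((m - 1) - thr + 1),
    1 - 0.95 * w / thr
  )
  da_tibble("ancomw", NA_character_, rownames(counts), as.numeric(w), score,
    is_score = TRUE
  )
}

#' Run a DA test with its default preprocessing transformation
#'
#' Dispatcher implementing the method battery under one contract. Default
#' transforms: rank/distribution tests (`wilcoxon`, `ks`) on TSS relative
#' abundances; linear-model-based tests (`ttest`, `lm`, `lm-fixed`, `lmm`,
#' `modt`) on TSS.log; `ancomw` on raw counts. Override with `transform`.
#'
#' @param counts integer count matrix (features x samples).
#' @param labels two-level group labels.
#' @param method one of `"wilcoxon"`, `"wilcoxon-blocked"`, `"ttest"`,
#'   `"ks"`, `"lm"`, `"lm-fixed"`, `"lmm"`, `"modt"`, `"ancomw"`.
#' @param confounder optional confounder labels for the adjusted variants.
#' @param transform `"auto"` (default) or any [normalize_counts()] method
#'   name, or `"none"`.
#' @param seed seed for stochastic transforms (rarefaction).
#' @param ... passed to the underlying test.
#' @return a DA result tibble.
#' @export
#' @examples
#' cm <- generate_baseline(baseline_spec(n_features = 40, n_samples = 60, seed = 2))
#' ds <- implant_signal(cm, seed = 5, scale = 5, shift = 0.2)
#' run_da_test(ds$counts, ds$labels, "wilcoxon") |> dplyr::arrange(p_raw)
run_da_test <- function(counts, labels,
                        method = c(
                          "wilcoxon", "wilcoxon-blocked", "ttest", "ks",
                          "lm", "lm-fixed", "lmm", "modt", "ancomw"
                        ),
                        confounder = NULL, transform = "auto", seed = 1L, ...) {
  method <- match.arg(method)
  if (transform == "auto") {
    transform <- switch(method,
      "wilcoxon" = "TSS", "wilcoxon-blocked" = "TSS", "ks" = "TSS",
      "ttest" = "TSS.log", "lm" = "TSS.log", "lm-fixed" = "TSS.log",
      "lmm" = "TSS.log", "modt" = "TSS.log", "ancomw" = "none"
    )
  }
  mat <- if (transform == "none") counts else normalize_counts(counts, transform, seed = seed)
  res <- switch(method,
    "wilcoxon" = da_wilcoxon(mat, labels, ...),
    "wilcoxon-blocked" = {
      if (is.null(confounder)) stop("wilcoxon-blocked requires a confounder", call. = FALSE)
      da_wilcoxon(mat, labels, block = confounder, ...)
    },
    "ttest" = da_ttest(mat, labels),
    "ks" = da_ks(mat, labels),
    "lm" = da_lm(mat, labels),
    "lm-fixed" = {
      if (is.null(confounder)) stop("lm-fixed requires a confounder", call. = FALSE)
      da_lm(mat, labels, covariate = confounder, covariate_role = "fixed")
    },
    "lmm" = {
      if (is.null(confounder)) stop("lmm requires a confounder", call. = FALSE)
      da_lm(mat, labels, covariate = confounder, covariate_role = "random")
    },
    "modt" = da_moderated_t(mat, labels),
    "ancomw" = da_ancom_w(counts, labels, ...)
  )
  res$method <- method
  res$transform <- transform
  res
}
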