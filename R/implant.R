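#' Randomly split samples into two balanced mock groups
#'
#' @param cm count matrix (features x samples).
#' @param seed integer seed.
#' @return factor of length `ncol(cm)` with levels `"1"` and `"2"`; group
#'   sizes differ by at most one.
#' @export
split_groups <- function(cm, seed) {
  assert_count_matrix(cm)
  n <- ncol(cm)
  if (n < 4) stop("need at least 4 samples to form two groups", call. = FALSE)
  n1 <- n %/% 2
  withr::with_seed(seed, idx <- sample.int(n, n1))
  g <- rep("2", n)
  g[idx] <- "1"
  factor(g, levels = c("1", "2"))
}

#' Select features to become differentially abundant
#'
#' Draws `round(fraction * n_features)` feature ids uniformly from the
#' eligible pool. With `mode = "low"` only low-abundance features are
#' eligible: those whose 75th percentile of counts across all samples is 0.
#'
#' @param cm count matrix.
#' @param fraction fraction of all features to select (default 0.1).
#' @param mode `"all"` (default) or `"low"`.
#' @param seed integer seed.
#' @return character vector of selected feature ids.
#' @export
select_da_features <- function(cm, fraction = 0.1, mode = c("all", "low"), seed = 1L) {
  assert_count_matrix(cm)
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  eligible <- rownames(cm)
  if (mode == "low") {
    q75 <- apply(cm, 1, stats::quantile, probs = 0.75, type = 7, names = FALSE)
    eligible <- rownames(cm)[q75 <= 0]
  }
  k <- round(fraction * nrow(cm))
  if (k == 0) return(character())
  if (length(eligible) < k) {
    stop(sprintf(
      "eligible pool (%d features, mode = '%s') smaller than requested %d",
      length(eligible), mode, k
    ), call. = FALSE)
  }
  withr::with_seed(seed, sel <- sample(eligible, k))
  sel
}

# per-feature target groups under the alternation rule: features sorted by id
# alternate between group 1 and group 2 (balanced), or all hit `group`
target_directions <- function(features, balanced = TRUE, group = 2L) {
  f <- sort(features)
  dir <- if (balanced) rep_len(c(1L, 2L), length(f)) else rep(as.integer(group), length(f))
  stats::setNames(dir, f)[features]
}

#' Implant a prevalence shift
#'
#' For each selected feature, a fraction `shift` of the non-zero entries in
#' the donor group (the group opposite the feature's target group) is
#' exchanged with zero entries in the target group, where possible: each
#' exchange moves one non-zero count into a zero slot of the target group and
#' zeroes the donor entry, so the feature's total zero count over all samples
#' is conserved.
#'
#' @param cm count matrix.
#' @param labels two-level group labels.
#' @param features feature ids to modify.
#' @param shift fraction in `[0, 1]` of donor non-zero entries to exchange.
#' @param direction named integer vector (1 or 2) of per-feature target
#'   groups; defaults to alternation over sorted ids.
#' @param seed integer seed.
#' @return the modified count matrix.
#' @export
implant_prevalence <- function(cm, labels, features, shift,
                               direction = target_directions(features), seed = 1L) {
  assert_count_matrix(cm)
  stopifnot(shift >= 0, shift <= 1, all(features %in% rownames(cm)))
  g <- as_group_factor(labels, n = ncol(cm))
  if (shift == 0 || length(features) == 0) return(cm)
  out <- cm
  withr::with_seed(seed, {
    for (f in features) {
      tgt <- which(as.integer(g) == direction[[f]])
      don <- which(as.integer(g) != direction[[f]])
      don_nz <- don[out[f, don] > 0]
      tgt_z <- tgt[out[f, tgt] == 0]
      k <- round_half_up(shift * length(don_nz))
      r <- min(k, length(tgt_z), length(don_nz))
      if (r > 0) {
        from <- if (length(don_nz) == 1) don_nz else sample(don_nz, r)
        to <- if (length(tgt_z) == 1) tgt_z else sample(tgt_z, r)
        out[f, to] <- out[f, from[seq_len(r)]]
        out[f, from[seq_len(r)]] <- 0L
      }
    }
  })
  out
}

#' Implant an abundance scaling effect
#'
#' Multiplies the non-zero counts of each selected feature in its target
#' group by `scale`. Scaled values are rounded back to integers with a floor
#' of 1, so scaling can never change which entries are zero.
#'
#' @inheritParams implant_prevalence
#' @param scale multiplier `>= 1`; `scale = 1` is the identity.
#' @param rounding `"half_up"` (default), `"floor"` or `"ceiling"`; all are
#'   followed by the floor-of-1 rule for non-zero entries.
#' @return the modified count matrix.
#' @export
implant_abundance <- function(cm, labels, features, scale,
                              direction = target_directions(features),
                              rounding = c("half_up", "floor", "ceiling")) {
  assert_count_matrix(cm)
  rounding <- match.arg(rounding)
  stopifnot(scale >= 1, all(features %in% rownames(cm)))
  g <- as_group_factor(labels, n = ncol(cm))
  if (scale == 1 || length(features) == 0) return(cm)
  rnd <- switch(rounding, half_up = round_half_up, floor = floor, ceiling = ceiling)
  out <- cm
  for (f in features) {
    tgt <- which(as.integer(g) == direction[[f]])
    nz <- tgt[out[f, tgt] > 0]
    out[f, nz] <- pmax(1, rnd(out[f, nz] * scale))
  }
  storage.mode(out) <- "integer"
  out
}

#' Implant a differential-abundance ground truth into a count table
#'
#' The core simulator: samples are split into two balanced mock groups, a
#' fraction of features is selected, a prevalence shift and an abundance
#' scaling are implanted toward each feature's target group, and the realized
#' effect sizes are recorded as ground truth. By default implanted features
#' alternate their target group (in sorted-id order) so that no systematic
#' total-count difference between groups is introduced. Selected features
#' whose realized |gFC| falls below `reject_gfc` are recorded but flagged as
#' rejected; at the null grid point (`scale = 1`, `shift = 0`) nothing is
#' implanted and all selected features are rejected (internal negative
#' control).
#'
#' @param cm baseline count matrix (pre-filtered).
#' @param seed integer seed; all internal randomness derives from it.
#' @param fraction fraction of features to implant (default 0.1).
#' @param mode feature eligibility, `"all"` or `"low"` (see
#'   [select_da_features()]).
#' @param scale abundance scaling factor `>= 1`.
#' @param shift prevalence shift fraction in `[0, 1]`.
#' @param balanced alternate target groups across implanted features
#'   (default `TRUE`); if `FALSE` all features target group 2.
#' @param reject_gfc |gFC| threshold below which an implanted feature is
#'   rejected from the ground truth (default 0.001).
#' @param rounding rounding policy for scaled counts, see
#'   [implant_abundance()].
#' @return a [sim_dataset()].
#' @export
#' @examples
#' cm <- generate_baseline(baseline_spec(n_features = 60, n_samples = 50, seed = 3))
#' ds <- implant_signal(cm, seed = 11, scale = 2, shift = 0.2)
#' ds
implant_signal <- function(cm, seed, fraction = 0.1, mode = "all",
                           scale = 1, shift = 0, balanced = TRUE,
                           reject_gfc = 0.001, rounding = "half_up") {
  assert_count_matrix(cm)
  labels <- split_groups(cm, seed = child_seed(seed, 1L))
  features <- select_da_features(cm, fraction = fraction, mode = mode, seed = child_seed(seed, 2L))
  build_implantation(cm, labels, features, seed,
    scale = scale, shift = shift,
    direction = target_directions(features, balanced = balanced),
    reject_gfc = reject_gfc, rounding = rounding,
    params = list(
      seed = seed, fraction = fraction, mode = mode, scale = scale,
      shift = shift, balanced = balanced, type = "implantation"
    )
  )
}

# shared implantation core: prevalence shift first, then abundance scaling,
# both toward the same per-feature target group; effect sizes recorded last
build_implantation <- function(cm, labels, features, seed, scale, shift,
                               direction, reject_gfc, rounding, params) {
  out <- implant_prevalence(cm, labels, features, shift,
    direction = direction, seed = child_seed(seed, 3L)
  )
  out <- implant_abundance(out, labels, features, scale,
    direction = direction, rounding = rounding
  )
  null_point <- (scale == 1 && shift == 0)
  if (length(features)) {
    eff <- feature_effects(out[features, , drop = FALSE], labels)
    truth <- tibble::tibble(
      feature_id = features,
      target_group = as.integer(direction[features]),
      abundance_scale = scale,
      prev_shift = shift,
      gfc = eff$gfc,
      prev_diff = eff$prev_diff,
      rejected = null_point | abs(eff$gfc) < reject_gfc
    )
  } else {
    truth <- empty_ground_truth()
  }
  sim_dataset(out, labels, truth = truth, params = params)
}

#' Implant a one-sided (compositional) signal
#'
#' All implanted features target the same group; afterwards every modified
#' sample is rarefied without replacement back to its original total count.
#' Raising some features while holding the library size fixed necessarily
#' depletes the background features of that group — the compositional
#' spill-over this mode is designed to produce. Only the implanted features
#' are marked as ground truth.
#'
#' @inheritParams implant_signal
#' @param group target group for all implanted features (default 2).
#' @return a [sim_dataset()].
#' @export
implant_compositional <- function(cm, seed, fraction = 0.1, mode = "all",
                                  scale = 1, shift = 0, group = 2L,
                                  reject_gfc = 0.001, rounding = "half_up") {
  assert_count_matrix(cm)
  labels <- split_groups(cm, seed = child_seed(seed, 1L))
  features <- select_da_features(cm, fraction = fraction, mode = mode, seed = child_seed(seed, 2L))
  direction <- target_directions(features, balanced = FALSE, group = group)
  orig_totals <- colSums(cm)
  ds <- build_implantation(cm, labels, features, seed,
    scale = scale, shift = shift, direction = direction,
    reject_gfc = reject_gfc, rounding = rounding,
    params = list(
      seed = seed, fraction = fraction, mode = mode, scale = scale,
      shift = shift, group = group, type = "compositional"
    )
  )
  new_totals <- colSums(ds$counts)
  inflated <- which(new_totals > orig_totals)
  if (length(inflated)) {
    ds$counts[, inflated] <- rarefy_counts(
      ds$counts[, inflated, drop = FALSE],
      depth = orig_totals[inflated], seed = child_seed(seed, 4L)
    )
  }
  ds
}
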