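#' Define a benchmark grid
#'
#' The full factorial design of the benchmark: abundance scaling factors,
#' prevalence shifts, implantation repeats, sample sizes and testing
#' subsamples, plus the master seed from which every task seed derives.
#' The defaults reproduce the full design (7 x 4 x 100 x 7 x 50 = 980,000
#' configurations per DA method).
#'
#' @param abundance_scales ordered abundance multipliers (default
#'   `c(1, 1.25, 1.5, 2, 5, 10, 20)`).
#' @param prev_shifts prevalence-shift fractions (default `c(0, .1, .2, .3)`).
#' @param n_implant_repeats implantation repeats per effect size (default 100).
#' @param sample_sizes even subsample sizes (default
#'   `c(12, 24, 50, 100, 200, 400, 800)`).
#' @param n_subsamples testing repeats per sample size (default 50).
#' @param master_seed integer master seed.
#' @return a `benchmark_grid` list.
#' @export
benchmark_grid <- function(abundance_scales = c(1, 1.25, 1.5, 2, 5, 10, 20),
                           prev_shifts = c(0, 0.1, 0.2, 0.3),
                           n_implant_repeats = 100,
                           sample_sizes = c(12, 24, 50, 100, 200, 400, 800),
                           n_subsamples = 50,
                           master_seed = 1L) {
  stopifnot(
    length(abundance_scales) >= 1, all(abundance_scales >= 1),
    length(prev_shifts) >= 1, all(prev_shifts >= 0 & prev_shifts <= 1),
    n_implant_repeats >= 1, length(sample_sizes) >= 1,
    all(sample_sizes %% 2 == 0), n_subsamples >= 1
  )
  structure(as.list(environment()), class = "benchmark_grid")
}

#' Enumerate every configuration of a benchmark grid
#'
#' Cartesian product in a fixed documented order (abundance scale slowest,
#' then prevalence shift, implantation repeat, sample size, subsample
#' fastest).
#'
#' @param grid a [benchmark_grid()].
#' @return tibble with one row per configuration; its row count equals the
#'   product of the grid dimensions.
#' @export
#' @examples
#' nrow(enumerate_configs(benchmark_grid())) # 980000
enumerate_configs <- function(grid) {
  stopifnot(inherits(grid, "benchmark_grid"))
  tidyr::expand_grid(
    abundance_scale = grid$abundance_scales,
    prev_shift = grid$prev_shifts,
    implant_repeat = seq_len(grid$n_implant_repeats),
    sample_size = grid$sample_sizes,
    subsample = seq_len(grid$n_subsamples)
  )
}

#' Generate shared test indices for all sample sizes and subsamples
#'
#' For each sample size `n` and each testing repeat, draws `n/2` sample
#' positions per group without replacement. The indices are what every DA
#' method consumes, guaranteeing byte-identical inputs across methods.
#'
#' @param labels two-level group labels of the simulated dataset.
#' @param sizes even sample sizes; each must satisfy
#'   `size/2 <= min(group sizes)`.
#' @param n_subsamples testing repeats per size.
#' @param seed integer seed.
#' @return tibble with columns `sample_size`, `subsample`, `position`.
#' @export
generate_test_indices <- function(labels, sizes, n_subsamples, seed = 1L) {
  g <- as_group_factor(labels)
  stopifnot(all(sizes %% 2 == 0))
  smallest <- min(table(g))
  if (any(sizes / 2 > smallest)) {
    stop(sprintf(
      "sample size %d exceeds availability (smallest group has %d samples)",
      min(sizes[sizes / 2 > smallest]), smallest
    ), call. = FALSE)
  }
  i1 <- which(g == levels(g)[1])
  i2 <- which(g == levels(g)[2])
  purrr::map_dfr(sizes, function(n) {
    purrr::map_dfr(seq_len(n_subsamples), function(s) {
      withr::with_seed(child_seed(seed, n, s), {
        pos <- c(sample(i1, n / 2), sample(i2, n / 2))
      })
      tibble::tibble(sample_size = n, subsample = s, position = pos)
    })
  })
}

# evaluation row that tolerates an empty truth (null grid point: any
# discovery is false, recall/AUROC undefined)
eval_row <- function(result, truth, alpha, adjust) {
  if (length(truth) == 0) {
    p_adj <- if (any(result$is_score)) result$p_raw else adjust_pvalues(result$p_raw, adjust)
    nd <- sum(p_adj < alpha)
    return(tibble::tibble(
      method = result$method[1], n_discoveries = nd,
      observed_fdr = as.numeric(nd > 0), recall = NA_real_, auroc = NA_real_
    ))
  }
  evaluate_result(result, truth, alpha = alpha, adjust = adjust)
}

#' Run a (scaled) signal-implantation benchmark
#'
#' Orchestrates the sweep: for every (abundance scale, prevalence shift,
#' implantation repeat) a dataset is implanted; shared test indices are
#' drawn once per dataset; every method is evaluated on identical subsampled
#' inputs. Per-task failures are recorded (metrics `NA`) without aborting
#' the sweep. With a `store`, simulations and results are persisted and a
#' re-run resumes past completed (method, configuration) pairs.
#'
#' @param baseline filtered baseline count matrix.
#' @param grid a [benchmark_grid()]; keep it small for interactive use.
#' @param methods DA method names (see [run_da_test()]).
#' @param store optional [sim_store()].
#' @param alpha discovery cutoff (default 0.05).
#' @param adjust `"BH"` or `"BY"`.
#' @param fraction,mode,balanced implantation parameters (see
#'   [implant_signal()]).
#' @return tibble of evaluation records: one row per (method, configuration)
#'   with `observed_fdr`, `recall`, `auroc`.
#' @export
run_benchmark <- function(baseline, grid, methods = "wilcoxon", store = NULL,
                          alpha = 0.05, adjust = "BH",
                          fraction = 0.1, mode = "all", balanced = TRUE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  assert_count_matrix(baseline, "baseline")
  done <- if (!is.null(store)) {
    purrr::map_dfr(intersect(methods, store_keys(store, "results")), function(m) {
      load_results(store, m)
    })
  } else {
    tibble::tibble()
  }
  rows <- list()
  for (i in seq_along(grid$abundance_scales)) {
    for (j in seq_along(grid$prev_shifts)) {
      for (r in seq_len(grid$n_implant_repeats)) {
        sim_seed <- child_seed(grid$master_seed, i, j, r)
        ds <- implant_signal(baseline, sim_seed,
          fraction = fraction, mode = mode,
          scale = grid$abundance_scales[i], shift = grid$prev_shifts[j],
          balanced = balanced
        )
        key <- sprintf("ab%g_prev%g_rep%03d", grid$abundance_scales[i], grid$prev_shifts[j], r)
        if (!is.null(store) && !key %in% store_keys(store)) {
          save_simulation(store, ds, key)
        }
        idx <- generate_test_indices(ds$labels, grid$sample_sizes,
          grid$n_subsamples,
          seed = child_seed(sim_seed, 99L)
        )
        truth <- truth_features(ds)
        for (n in grid$sample_sizes) {
          for (s in seq_len(grid$n_subsamples)) {
            pos <- idx$position[idx$sample_size == n & idx$subsample == s]
            sub <- ds$counts[, pos, drop = FALSE]
            lab <- ds$labels[pos]
            for (m in methods) {
              if (nrow(done) > 0 && any(
                done$method == m & done$abundance_scale == grid$abundance_scales[i] &
                  done$prev_shift == grid$prev_shifts[j] & done$implant_repeat == r &
                  done$sample_size == n & done$subsample == s
              )) {
                next
              }
              ev <- tryCatch(
                eval_row(
                  run_da_test(sub, lab, m, seed = child_seed(sim_seed, n, s)),
                  truth,
                  alpha = alpha, adjust = adjust
                ),
                error = function(e) {
                  tibble::tibble(
                    method = m, n_discoveries = NA_integer_,
                    observed_fdr = NA_real_, recall = NA_real_, auroc = NA_real_
                  )
                }
              )
              rows[[length(rows) + 1]] <- tibble::tibble(
                abundance_scale = grid$abundance_scales[i],
                prev_shift = grid$prev_shifts[j],
                implant_repeat = r, sample_size = n, subsample = s, ev
              )
            }
          }
        }
      }
    }
  }
  new <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(done, new)
  out <- dplyr::arrange(
    out, .data$method, .data$abundance_scale, .data$prev_shift,
    .data$implant_repeat, .data$sample_size, .data$subsample
  )
  if (!is.null(store) && nrow(out) > 0) {
    for (m in unique(out$method)) {
      save_results(store, dplyr::filter(out, .data$method == m), m)
    }
  }
  class(out) <- c("da_benchmark", class(out))
  out
}

#' Summarise benchmark records per method and setting
#'
#' @param results tibble from [run_benchmark()].
#' @return tibble with mean/sd of observed FDR, recall and AUROC per
#'   (method, abundance scale, prevalence shift, sample size), plus the
#'   FDR-control sufficiency flag per method.
#' @export
summarize_benchmark <- function(results) {
  smry <- results |>
    dplyr::group_by(.data$method, .data$abundance_scale, .data$prev_shift, .data$sample_size) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_fdr = mean(.data$observed_fdr, na.rm = TRUE),
      sd_fdr = stats::sd(.data$observed_fdr, na.rm = TRUE),
      mean_recall = mean(.data$recall, na.rm = TRUE),
      mean_auroc = mean(.data$auroc, na.rm = TRUE),
      .groups = "drop"
    )
  flags <- smry |>
    dplyr::filter(.data$abundance_scale > 1 | .data$prev_shift > 0) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(fdr_control = fdr_control_flag(.data$mean_fdr), .groups = "drop")
  out <- dplyr::left_join(smry, flags, by = "method")
  class(out) <- c("benchmark_summary", class(out))
  out
}

#' @export
glance.da_benchmark <- function(x, ...) {
  x |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_configs = dplyr::n(),
      mean_fdr = mean(.data$observed_fdr, na.rm = TRUE),
      mean_recall = mean(.data$recall, na.rm = TRUE),
      mean_auroc = mean(.data$auroc, na.rm = TRUE)
    )
}
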