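# ggplot2 helpers for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed FDR and recall across sample sizes
#'
#' @param object a `benchmark_summary` from [summarize_benchmark()].
#' @param metric `"mean_fdr"`, `"mean_recall"` or `"mean_auroc"`.
#' @param ... unused.
#' @return a ggplot: one line per method, faceted by effect size.
#' @export
autoplot.benchmark_summary <- function(object, metric = "mean_fdr", ...) {
  stopifnot(metric %in% c("mean_fdr", "mean_recall", "mean_auroc"))
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample_size, y = .data[[metric]],
    colour = .data$method, group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(breaks = unique(object$sample_size)) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$prev_shift),
      cols = ggplot2::vars(.data$abundance_scale),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "sample size", y = metric) +
    ggplot2::theme_bw()
  if (metric == "mean_fdr") {
    p <- p + ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed", colour = "grey40")
  }
  p
}

#' Volcano-style plot of one DA result against the ground truth
#'
#' @param result DA result tibble from [run_da_test()].
#' @param effects per-feature effects from [feature_effects()] on the same
#'   dataset.
#' @param truth ground-truth feature ids to highlight.
#' @param alpha nominal cutoff line (default 0.05).
#' @return a ggplot of gFC versus -log10 p, truth features highlighted.
#' @export
plot_da_result <- function(result, effects, truth, alpha = 0.05) {
  df <- dplyr::left_join(result, effects, by = "feature_id") |>
    dplyr::mutate(implanted = .data$feature_id %in% truth)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gfc, y = -log10(pmax(.data$p_raw, 1e-16)),
    colour = .data$implanted
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#1b9e77")) +
    ggplot2::labs(x = "generalized fold change (log10)", y = "-log10 raw p") +
    ggplot2::theme_bw()
}

#' Compare sparsity and feature-variance distributions of real and simulated data
#'
#' @param real,sim count matrices.
#' @return a two-panel ggplot (sample sparsity densities; feature
#'   log-variance densities).
#' @export
plot_realism <- function(real, sim) {
  sv_r <- sparsity_and_variance(real)
  sv_s <- sparsity_and_variance(sim)
  df <- dplyr::bind_rows(
    tibble::tibble(origin = "real", what = "sample sparsity", value = sv_r$sample$sparsity),
    tibble::tibble(origin = "simulated", what = "sample sparsity", value = sv_s$sample$sparsity),
    tibble::tibble(origin = "real", what = "feature log-variance", value = sv_r$feature$log_var),
    tibble::tibble(origin = "simulated", what = "feature log-variance", value = sv_s$feature$log_var)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$origin)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), scales = "free") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = NULL, fill = NULL)
}
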