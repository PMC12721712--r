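#' Plot an RSA timecourse
#'
#' Group-mean coefficient with a +/- SEM ribbon over time; a dashed line
#' marks zero and a dotted line stimulus onset.
#'
#' @param object An [rsa_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_timecourse <- function(object, ...) {
  d <- tidy(object)
  s <- dplyr::summarise(dplyr::group_by(d, .data$time_ms),
                        mean_r = mean(.data$r),
                        sem = stats::sd(.data$r) / sqrt(dplyr::n()),
                        .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_ms, y = .data$mean_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sem,
                                      ymax = .data$mean_r + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)",
                  y = if (length(object$controls)) "partial Spearman r" else "Spearman r",
                  title = object$target,
                  subtitle = if (length(object$controls))
                    paste("controlling:", paste(object$controls, collapse = ", "))
                  else NULL) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap peak latencies
#'
#' Group-mean latency with a +/- SEM error bar per feature, over the
#' per-subject bootstrap-mean latencies.
#'
#' @param latencies Named list of [bootstrap_peak_latency()] results.
#' @return A ggplot object.
#' @export
plot_peak_latencies <- function(latencies) {
  d <- purrr::map_dfr(latencies, glance, .id = "feature")
  subj <- purrr::map_dfr(latencies, tidy, .id = "feature")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$group_mean_ms)) +
    ggplot2::geom_jitter(data = subj,
                         ggplot2::aes(y = .data$latency_ms),
                         width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$group_mean_ms - .data$group_sem_ms,
      ymax = .data$group_mean_ms + .data$group_sem_ms)) +
    ggplot2::labs(x = NULL, y = "peak latency (ms)") +
    ggplot2::theme_minimal()
}

#' Heatmap of an RDM
#'
#' Tile plot of the dissimilarity matrix, optionally histogram-equalized to
#' percentile units for display (the inference pathways never use the
#' equalized values).
#'
#' @param x An [rdm].
#' @param percentile Display percentile-equalized values.
#' @return A ggplot object.
#' @export
plot_rdm <- function(x, percentile = TRUE) {
  stopifnot(inherits(x, "rdm"))
  shown <- if (percentile) percentile_equalize(x) else x
  d <- tidyr::expand_grid(condition_a = x$ids, condition_b = x$ids)
  d$value <- as.vector(t(shown$values))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition_b, y = .data$condition_a,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(x$ids)) +
    ggplot2::scale_fill_viridis_c(
      name = if (percentile) "percentile" else x$kind) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a noise ceiling band over RSA timecourses
#'
#' @param ceiling A [noise_ceiling()] tibble.
#' @return A ggplot object.
#' @export
plot_noise_ceiling <- function(ceiling) {
  ggplot2::ggplot(ceiling, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "Spearman r (ceiling band)") +
    ggplot2::theme_minimal()
}
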