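#' Plot a task schedule's probability trajectories
#'
#' @param object A `task_schedule` tibble.
#' @param ... Unused.
#' @return A ggplot: per-valence scheduled probability of the outcome on
#'   shape A over trials, with block boundaries.
#' @exportS3Method ggplot2::autoplot
autoplot.task_schedule <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "trial", win = "p_win_A", loss = "p_loss_A"),
    c("win", "loss"), names_to = "valence", values_to = "p")
  nb <- attr(object, "config")$n_trials_per_block %||% 80L
  ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$p,
                                     colour = .data$valence)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = c(nb, 2 * nb) + 0.5, linetype = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "P(outcome on shape A)",
                  colour = "valence") +
    ggplot2::theme_minimal()
}

#' Plot learning-rate adjustments by group
#'
#' @param adj Output of [adjustment_table()].
#' @return A ggplot: per-valence adjustment distributions by group.
#' @export
plot_adjustment <- function(adj) {
  long <- adjustment_long(adj)
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$adjustment,
                                     fill = .data$valence)) +
    ggplot2::geom_violin(alpha = 0.5, position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.08, dodge.width = 0.8), size = 0.7, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "learning-rate adjustment (volatile - stable)") +
    ggplot2::theme_minimal()
}

#' Plot per-group mean pupil subtraction series
#'
#' @param series Long tibble `subject_id`, `group`, `valence`, `time`,
#'   `value` (e.g. the `subtraction` element of [condition_timeseries()]
#'   joined with group labels).
#' @return A ggplot: group mean with standard-error ribbon, one facet per
#'   valence.
#' @export
plot_condition_series <- function(series) {
  summ <- dplyr::summarise(
    dplyr::group_by(series, .data$group, .data$valence, .data$time),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$time, .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~ .data$valence) +
    ggplot2::labs(x = "time from outcome onset (ms)",
                  y = "volatile - stable pupil contrast (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot pointwise F curves and significant clusters of a cluster test
#'
#' @param object A `cluster_result` from [cluster_permutation_test()].
#' @param ... Unused.
#' @return A ggplot of the pointwise F statistic per effect with the
#'   cluster-forming threshold and significant clusters shaded.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  pw <- attr(object, "pointwise")
  curves <- purrr::imap_dfr(pw$observed, function(o, nm) {
    tibble::tibble(effect = nm, time = pw$times, F = o$F,
                   crit = pw$crit[[nm]])
  })
  sig <- object[object$p_value < 0.05, ]
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$crit), linetype = 2) +
    ggplot2::facet_wrap(~ .data$effect, scales = "free_y") +
    ggplot2::labs(x = "time from outcome onset (ms)", y = "pointwise F") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "red")
  }
  p
}
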