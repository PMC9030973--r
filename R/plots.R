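# Figures: profile trajectories and outcome mean trends.

#' Plot cluster-mean weekly trajectories
#'
#' Mean weekly activity level per cluster over the trajectory window,
#' faceted by dimension (therapy, social) — the visual signature of each
#' engagement profile.
#'
#' @param solution A `cluster_solution`.
#' @param tm Optional `trajectory_matrix` (adds cluster sizes to labels).
#' @return A ggplot object.
#' @export
plot_profile_trajectories <- function(solution, tm = NULL) {
  ct <- centroid_trajectories(solution)
  sizes <- solution$n_per_cluster
  ct$profile <- factor(sprintf("profile %d (n=%d)", ct$cluster, sizes[ct$cluster]))
  ct$dimension <- factor(ct$dimension, levels = c("therapy", "social"))
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$week, y = .data$level,
                                   colour = .data$profile)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~dimension) +
    ggplot2::scale_y_continuous(limits = c(1, 4),
                                breaks = 1:4,
                                labels = c("inactive", "passive",
                                           "engaged/moderate", "high/active")) +
    ggplot2::labs(x = "week of trial involvement", y = "mean activity level",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot model-implied outcome trends
#'
#' Cell means with 95% CIs per group at baseline and 6 months, from a
#' fitted [fit_group_time_model()] result.
#'
#' @param fit A `mixed_model_result` with cell means.
#' @return A ggplot object.
#' @export
plot_outcome_trends <- function(fit) {
  cm <- fit$cell_means
  if (is.null(cm)) stopf("fit has no cell means (refit with cell_means = TRUE)")
  cm$months <- ifelse(cm$time == "t0", 0, 6)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$months, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::scale_x_continuous(breaks = c(0, 6),
                                labels = c("baseline", "6 months")) +
    ggplot2::labs(x = NULL, y = fit$outcome_name, colour = NULL,
                  title = sprintf("Model-implied means: %s", fit$outcome_name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
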