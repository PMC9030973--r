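# End-to-end pipeline: simulate -> categorize -> cluster -> analyze.

#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end run: cohort sizes, the
#' trajectory window, clustering controls and model options. The
#' configuration is hashable, so every artifact the pipeline writes can
#' declare the exact configuration and seed that produced it.
#'
#' @param output_dir Directory for all artifacts.
#' @param seed Integer seed driving every stage.
#' @param n_users,n_tau,n_days Cohort sizes and days of involvement.
#' @param start_day,n_weeks Trajectory window (default days 2-155 = 22
#'   weeks).
#' @param k_range,n_restarts,min_cluster_size,n_resamples,resample_frac
#'   Clustering and selection controls (see [select_solution()]).
#' @param comparison `"profiles"` (profiles against each other),
#'   `"each-vs-tau"`, or `"both"`.
#' @param baseline_covariate Use the ANCOVA-style model variant.
#' @param p_adjust Apply Benjamini-Hochberg across outcomes within each
#'   comparison (off by default; the report always carries a
#'   multiple-comparisons caveat).
#' @param missing_rate Outcome missingness passed to the generator.
#' @param plots Write trajectory / trend figures (PNG).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "engagetraj_run", seed = 1L,
                            n_users = 82L, n_tau = 84L, n_days = 155L,
                            start_day = 2L, n_weeks = 22L,
                            k_range = 2:4, n_restarts = 100L,
                            min_cluster_size = 0.15, n_resamples = 100L,
                            resample_frac = 0.8,
                            comparison = c("both", "profiles", "each-vs-tau"),
                            baseline_covariate = FALSE, p_adjust = FALSE,
                            missing_rate = 0, plots = TRUE) {
  comparison <- match.arg(comparison)
  if (n_days < start_day + 7 * n_weeks - 1)
    stopf("n_days = %d cannot fill the %d-week window starting at day %d",
          n_days, n_weeks, start_day)
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              n_users = as.integer(n_users), n_tau = as.integer(n_tau),
              n_days = as.integer(n_days), start_day = as.integer(start_day),
              n_weeks = as.integer(n_weeks), k_range = as.integer(k_range),
              n_restarts = as.integer(n_restarts),
              min_cluster_size = min_cluster_size,
              n_resamples = as.integer(n_resamples),
              resample_frac = resample_frac, comparison = comparison,
              baseline_covariate = baseline_covariate, p_adjust = p_adjust,
              missing_rate = missing_rate, plots = plots)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys match the arguments of
#'   `pipeline_config()` (`k_range` may be given as `k_min` / `k_max`).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$k_min) || !is.null(y$k_max)) {
    y$k_range <- seq(y$k_min %||% 2L, y$k_max %||% 4L)
    y$k_min <- NULL; y$k_max <- NULL
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  flat <- config[sort(setdiff(names(config), "output_dir"))]
  fnv1a_hash(paste(names(flat), vapply(flat, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=", collapse = ";"))
}

provenance_header <- function(config) {
  sprintf("engagetraj config=%s seed=%d", config_hash(config), config$seed)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full engagement-profiling pipeline
#'
#' Executes simulate -> trajectories -> cluster -> analyze deterministically
#' for the configured seed, writing `usage_log.csv`, `outcomes.csv`,
#' `truth.csv`, `trajectories.csv`, `solution.json`, `results.json`, a
#' Markdown `report.md`, and (optionally) profile-trajectory and mean-trend
#' figures to the output directory. Every artifact declares the config hash
#' and seed that produced it. Any stage failure aborts with a stage-tagged
#' error.
#'
#' @param config A [pipeline_config()].
#' @return List with the cohort, trajectory matrix, selection, analysis
#'   results and artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  header <- provenance_header(config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  cohort <- run_stage("simulate", {
    ch <- simulate_cohort(n_users = config$n_users, n_tau = config$n_tau,
                          n_days = config$n_days, seed = config$seed,
                          missing_rate = config$missing_rate)
    write_cohort(ch, config$output_dir, header = header)
    stage_log("simulate", "%d intervention users, %d TAU, %d usage rows",
              config$n_users, config$n_tau, nrow(ch$usage_log))
    ch
  })

  tm <- run_stage("trajectories", {
    tm <- build_trajectory_matrix(cohort$usage_log, config$start_day,
                                  config$n_weeks)
    write_trajectories(tm, file.path(config$output_dir, "trajectories.csv"),
                       header = header)
    stage_log("trajectories", "%d users x 2 x %d weeks (%d all-inactive)",
              length(tm$users), tm$n_weeks, length(tm$inactive))
    tm
  })

  sel <- run_stage("cluster", {
    sel <- select_solution(tm, k_range = config$k_range,
                           min_cluster_size = config$min_cluster_size,
                           n_restarts = config$n_restarts,
                           n_resamples = config$n_resamples,
                           frac = config$resample_frac,
                           seed = fan_out_seed(config$seed, 17))
    write_solution_json(sel, file.path(config$output_dir, "solution.json"),
                        config)
    stage_log("cluster", "candidates k = %s; chosen k = %s",
              paste(config$k_range, collapse = ","),
              ifelse(is.na(sel$k), "none admissible", sel$k))
    sel
  })

  results <- run_stage("analyze", {
    if (is.na(sel$k))
      stopf("no admissible cluster solution to analyze")
    outcomes <- assign_groups(cohort$outcomes, sel$chosen$labels)
    res <- analyze_outcomes(outcomes, config)
    write_results_json(res, file.path(config$output_dir, "results.json"),
                       config)
    stage_log("analyze", "%d outcome(s), comparison = %s",
              length(unique(cohort$outcomes$outcome_name)), config$comparison)
    res
  })

  paths <- run_stage("report", {
    p <- write_report(config, cohort, tm, sel, results)
    stage_log("report", "report written to %s", p["report"])
    p
  })

  invisible(list(config = config, cohort = cohort, trajectories = tm,
                 selection = sel, results = results, paths = paths))
}

profile_levels <- function(outcomes) {
  g <- unique(outcomes$group)
  c(sort(setdiff(g, "TAU")), intersect("TAU", g))
}

analyze_outcomes <- function(outcomes, config) {
  outcome_names <- sort(unique(outcomes$outcome_name))
  profiles <- sort(setdiff(unique(outcomes$group), "TAU"))
  res <- list()
  if (config$comparison %in% c("both", "profiles")) {
    res$profiles <- lapply(outcome_names, function(on)
      fit_group_time_model(outcomes[outcomes$group != "TAU", ], on,
                           groups = profiles,
                           baseline_covariate = config$baseline_covariate))
    names(res$profiles) <- outcome_names
  }
  if (config$comparison %in% c("both", "each-vs-tau")) {
    res$each_vs_tau <- list()
    for (pr in profiles) {
      fits <- lapply(outcome_names, function(on)
        fit_group_time_model(outcomes[outcomes$group %in% c(pr, "TAU"), ], on,
                             groups = c(pr, "TAU"),
                             baseline_covariate = config$baseline_covariate))
      names(fits) <- outcome_names
      res$each_vs_tau[[pr]] <- fits
    }
  }
  res$interaction_table <- interaction_table(res, config)
  res
}

interaction_row <- function(fit, comparison) {
  it <- fit$tests[fit$tests$term == "group:time", ]
  data.frame(comparison = comparison, outcome = fit$outcome_name,
             F = it$F, df1 = it$df1, df2 = it$df2, p = it$p,
             singular = fit$singular)
}

interaction_table <- function(res, config) {
  rows <- list()
  for (fit in res$profiles %||% list())
    rows[[length(rows) + 1]] <- interaction_row(fit, "profiles")
  for (pr in names(res$each_vs_tau %||% list()))
    for (fit in res$each_vs_tau[[pr]])
      rows[[length(rows) + 1]] <- interaction_row(fit, paste0(pr, " vs TAU"))
  tab <- do.call(rbind, rows)
  if (isTRUE(config$p_adjust) && !is.null(tab)) {
    tab$p_adj <- stats::ave(tab$p, tab$comparison,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  tab
}

write_solution_json <- function(sel, path, config) {
  chosen <- sel$chosen
  obj <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed),
    chosen_k = if (is.na(sel$k)) NULL else sel$k,
    candidates = sel$candidates,
    rationale = sel$rationale,
    labels = if (!is.null(chosen))
      as.list(stats::setNames(unname(chosen$labels), names(chosen$labels))),
    centroids = if (!is.null(chosen)) unname(apply(chosen$centroids, 1, c,
                                                   simplify = FALSE)),
    n_per_cluster = if (!is.null(chosen)) chosen$n_per_cluster,
    stability = lapply(sel$stability, function(s)
      list(k = s$k, mean_rand = s$mean_rand, mean_ari = s$mean_ari,
           rand_scores = s$rand_scores)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

model_to_list <- function(fit) {
  list(outcome = fit$outcome_name,
       tests = fit$tests,
       cell_means = fit$cell_means,
       singular = fit$singular,
       n_dropped = fit$n_dropped)
}

write_results_json <- function(results, path, config) {
  obj <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed),
    caveat = paste("P values are not corrected for multiple comparisons",
                   "unless p_adjust is enabled; interpret with caution."),
    profiles = lapply(results$profiles %||% list(), model_to_list),
    each_vs_tau = lapply(results$each_vs_tau %||% list(), function(fits)
      lapply(fits, model_to_list)),
    interaction_table = results$interaction_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

write_report <- function(config, cohort, tm, sel, results) {
  paths <- c(report = file.path(config$output_dir, "report.md"))
  lines <- c(
    "# Engagement-profiling pipeline report",
    "",
    sprintf("- config hash: `%s`", config_hash(config)),
    sprintf("- seed: %d", config$seed),
    sprintf("- cohort: %d intervention users (%d user-days), %d TAU",
            config$n_users, nrow(cohort$usage_log), config$n_tau),
    sprintf("- trajectory window: days %d-%d (%d weeks); %d user(s) with no in-window activity",
            config$start_day, config$start_day + 7 * config$n_weeks - 1,
            config$n_weeks, length(tm$inactive)),
    "",
    "## Cluster selection",
    "",
    knit_table(within(sel$candidates, {
      calinski_harabasz <- round(calinski_harabasz, 2)
      ray_turi <- round(ray_turi, 3)
      davies_bouldin <- round(davies_bouldin, 3)
      mean_rand <- round(mean_rand, 3)
      mean_ari <- round(mean_ari, 3)
    })[, c("k", "calinski_harabasz", "ray_turi", "davies_bouldin",
           "min_size", "excluded", "mean_rand", "votes")]),
    "",
    paste("-", sel$rationale),
    "",
    "## Group-by-time interactions",
    "",
    "*P values are uncorrected for multiple comparisons unless `p_adjust` is set.*",
    "")
  it <- results$interaction_table
  if (!is.null(it)) {
    it$F <- round(it$F, 3); it$df2 <- round(it$df2, 1); it$p <- signif(it$p, 3)
    lines <- c(lines, knit_table(it), "")
  }
  if (isTRUE(config$plots)) {
    fig1 <- file.path(config$output_dir, "profile_trajectories.png")
    ggplot2::ggsave(fig1, plot_profile_trajectories(sel$chosen, tm),
                    width = 8, height = 4, dpi = 120)
    paths["profile_trajectories"] <- fig1
    lines <- c(lines, "## Profile trajectories", "",
               "![profile trajectories](profile_trajectories.png)", "")
    for (on in names(results$profiles %||% list())) {
      fit <- results$profiles[[on]]
      if (is.null(fit$cell_means)) next
      fig <- file.path(config$output_dir, sprintf("trend_%s.png", on))
      ggplot2::ggsave(fig, plot_outcome_trends(fit), width = 6, height = 4,
                      dpi = 120)
      paths[paste0("trend_", on)] <- fig
      lines <- c(lines, sprintf("![%s trends](trend_%s.png)", on, on), "")
    }
  }
  writeLines(lines, paths["report"])
  paths
}

knit_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
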