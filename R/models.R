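# Profile characterization and mixed-model outcome analysis.
#
# The predictive analysis fits, per outcome,
#   value ~ group * time + sex + age + dup_days + (1 | user_id)
# by REML, with time categorical (baseline, 6 months). Baseline differences
# are accommodated by the cell-means structure of the model (baseline is the
# reference timepoint); an ANCOVA-style variant that conditions the 6-month
# value on the baseline value is available behind `baseline_covariate`.
# Omnibus F tests are Type III with Satterthwaite denominator degrees of
# freedom; post-hoc single-df contrasts reuse the fitted coefficient
# covariance.

#' Attach engagement-profile labels to an outcomes table
#'
#' Replaces the `group` column of a long outcomes table with profile labels
#' from a clustering solution for intervention users; TAU rows keep the
#' label `"TAU"`. Intervention users absent from `labels` are dropped with
#' a message.
#'
#' @param outcomes Long-format outcomes data frame (see
#'   [generate_outcomes()]).
#' @param labels Named integer vector (user -> cluster, as in
#'   `cluster_solution$labels`) or data frame `user_id`, `group`.
#' @param profile_names Optional character vector naming clusters 1..k.
#' @return The outcomes data frame with an updated `group` column.
#' @export
assign_groups <- function(outcomes, labels, profile_names = NULL) {
  if (is.data.frame(labels)) {
    map <- stats::setNames(as.character(labels$group), labels$user_id)
  } else {
    lab <- labels
    if (!is.null(profile_names)) {
      map <- stats::setNames(profile_names[lab], names(lab))
    } else {
      map <- stats::setNames(paste0("profile_", lab), names(lab))
    }
  }
  is_tau <- outcomes$arm == "TAU"
  known <- is_tau | outcomes$user_id %in% names(map)
  if (any(!known)) {
    message(sprintf("dropping %d rows for %d intervention user(s) without a profile label",
                    sum(!known), length(unique(outcomes$user_id[!known]))))
    outcomes <- outcomes[known, ]
    is_tau <- outcomes$arm == "TAU"
  }
  outcomes$group <- ifelse(is_tau, "TAU", map[as.character(outcomes$user_id)])
  outcomes
}

#' Fit the group-by-time linear mixed model for one outcome
#'
#' Fits `value ~ group * time + covariates + (1 | user_id)` by REML for the
#' requested outcome and groups, reporting Type III F tests (Satterthwaite
#' denominator df) for group, time and the group-by-time interaction, fixed
#' effects with standard errors, and model-implied cell means per
#' group-by-time cell with 95% CIs (covariates held at their means). Rows
#' with missing outcome or covariate values are dropped and counted. A
#' boundary fit with zero random-intercept variance is flagged, not treated
#' as failure; if the mixed fit fails entirely (e.g. degenerate
#' zero-residual data) an ordinary least-squares fallback without the random
#' intercept is used and flagged.
#'
#' @param data Long-format outcomes data frame with columns `user_id`,
#'   `group`, `timepoint` (0/6), `outcome_name`, `value` and any covariates.
#' @param outcome_name Which outcome to model.
#' @param groups Optional subset (and ordering: first level is the
#'   reference) of group labels; default all groups present.
#' @param covariates Covariate columns to adjust for; those absent from
#'   `data` are ignored (default `sex`, `age`, `dup_days`).
#' @param cell_means Compute model-implied cell means via emmeans (default
#'   `TRUE`; turn off to speed up simulation loops).
#' @param baseline_covariate Use the ANCOVA-style variant instead: the
#'   6-month value regressed on group plus the baseline value (no random
#'   intercept; post-hoc time contrasts unavailable).
#' @return Object of class `mixed_model_result`: `outcome_name`, `fixed`
#'   (coefficient table), `tests` (Type III F table), `cell_means`,
#'   `singular`, `n_dropped`, `groups`, `model`, plus internals used by the
#'   post-hoc functions.
#' @seealso [posthoc_time_within_group()], [posthoc_group_at_time()]
#' @export
fit_group_time_model <- function(data, outcome_name,
                                 groups = NULL,
                                 covariates = c("sex", "age", "dup_days"),
                                 cell_means = TRUE,
                                 baseline_covariate = FALSE) {
  d <- data[data$outcome_name == outcome_name, ]
  if (nrow(d) == 0) stopf("no rows for outcome '%s'", outcome_name)
  if (is.null(groups)) groups <- sort(unique(as.character(d$group)))
  if (length(groups) < 2) stopf("need at least 2 groups")
  d <- d[d$group %in% groups, ]
  d$group <- factor(d$group, levels = groups)
  d$time <- factor(ifelse(d$timepoint == 0, "t0", "t6"), levels = c("t0", "t6"))
  if (!all(c("t0", "t6") %in% d$time)) stopf("both timepoints must be present")
  covariates <- intersect(covariates, names(d))
  keep <- stats::complete.cases(d[, c("value", covariates)])
  n_dropped <- sum(!keep)
  d <- d[keep, ]
  d$user_id <- factor(d$user_id)

  if (baseline_covariate) return(fit_ancova_variant(d, outcome_name, covariates,
                                                    groups, n_dropped))

  rhs <- paste(c("group * time", covariates), collapse = " + ")
  fixed_formula <- stats::as.formula(paste("value ~", rhs))
  full_formula <- stats::as.formula(paste("value ~", rhs, "+ (1 | user_id)"))

  model <- tryCatch(
    lmerTest::lmer(full_formula, data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(model, "error")) {
    # degenerate data (e.g. zero residual variance): ordinary least squares
    model <- stats::lm(fixed_formula, data = d)
    singular <- TRUE
    tests <- ols_type3(model)
    beta <- stats::coef(model)
    fixed <- summary(model)$coefficients
  } else {
    singular <- lme4::isSingular(model)
    a3 <- stats::anova(model, type = 3, ddf = "Satterthwaite")
    tests <- data.frame(term = rownames(a3), F = a3[["F value"]],
                        df1 = a3[["NumDF"]], df2 = a3[["DenDF"]],
                        p = a3[["Pr(>F)"]], row.names = NULL)
    beta <- lme4::fixef(model)
    fixed <- stats::coef(summary(model))
  }

  res <- structure(list(
    outcome_name = outcome_name, groups = groups, fixed = fixed,
    tests = tests, singular = singular, n_dropped = n_dropped,
    model = model, beta = beta, vcov = as.matrix(stats::vcov(model)),
    fixed_rhs = stats::as.formula(paste("~", rhs)),
    covariate_means = if (length(covariates))
      colMeans(d[!duplicated(d$user_id), covariates, drop = FALSE])
    else NULL,
    covariates = covariates, variant = "lmm",
    cell_means = NULL), class = "mixed_model_result")
  if (cell_means) res$cell_means <- compute_cell_means(res)
  res
}

fit_ancova_variant <- function(d, outcome_name, covariates, groups, n_dropped) {
  wide <- merge(
    d[d$time == "t0", c("user_id", "group", "value", covariates)],
    d[d$time == "t6", c("user_id", "value")],
    by = "user_id", suffixes = c("_t0", "_t6"))
  rhs <- paste(c("group", "value_t0", covariates), collapse = " + ")
  model <- stats::lm(stats::as.formula(paste("value_t6 ~", rhs)), data = wide)
  tests <- ols_type3(model)
  structure(list(outcome_name = outcome_name, groups = groups,
                 fixed = summary(model)$coefficients, tests = tests,
                 singular = FALSE, n_dropped = n_dropped, model = model,
                 beta = stats::coef(model), vcov = stats::vcov(model),
                 variant = "ancova", cell_means = NULL),
            class = "mixed_model_result")
}

# Type III F tests for an lm via term-wise general linear hypotheses.
ols_type3 <- function(model) {
  asg <- attr(stats::model.matrix(model), "assign")
  terms_lab <- attr(stats::terms(model), "term.labels")
  beta <- stats::coef(model)
  V <- stats::vcov(model)
  df2 <- stats::df.residual(model)
  rows <- lapply(seq_along(terms_lab), function(i) {
    idx <- which(asg == i)
    L <- matrix(0, length(idx), length(beta))
    L[cbind(seq_along(idx), idx)] <- 1
    est <- L %*% beta
    Fv <- drop(t(est) %*% solve(L %*% V %*% t(L)) %*% est) / length(idx)
    data.frame(term = terms_lab[i], F = Fv, df1 = length(idx), df2 = df2,
               p = stats::pf(Fv, length(idx), df2, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# Model-matrix row for one (group, time) cell with covariates at their means.
design_row <- function(result, group, time) {
  nd <- data.frame(group = factor(group, levels = result$groups),
                   time = factor(time, levels = c("t0", "t6")))
  for (cv in result$covariates) nd[[cv]] <- result$covariate_means[[cv]]
  mm <- stats::model.matrix(result$fixed_rhs, nd)
  stopifnot(identical(colnames(mm), names(result$beta)))
  drop(mm)
}

contrast_test <- function(result, L) {
  est <- sum(L * result$beta)
  se <- sqrt(drop(t(L) %*% result$vcov %*% L))
  if (inherits(result$model, "lmerModLmerTest")) {
    ct <- lmerTest::contest1D(result$model, L)
    data.frame(estimate = ct$Estimate, se = ct$`Std. Error`, F = ct$`t value`^2,
               df1 = 1, df2 = ct$df,
               p = ct$`Pr(>|t|)`)
  } else {
    df2 <- stats::df.residual(result$model)
    tv <- est / se
    data.frame(estimate = est, se = se, F = tv^2, df1 = 1, df2 = df2,
               p = 2 * stats::pt(abs(tv), df2, lower.tail = FALSE))
  }
}

compute_cell_means <- function(result) {
  grid <- expand.grid(group = result$groups, time = c("t0", "t6"),
                      stringsAsFactors = FALSE)
  if (inherits(result$model, "lmerModLmerTest")) {
    em <- summary(emmeans::emmeans(result$model, ~ group * time,
                                   lmer.df = "satterthwaite",
                                   lmerTest.limit = 1e5))
    data.frame(group = as.character(em$group), time = as.character(em$time),
               mean = em$emmean, se = em$SE, df = em$df,
               lower = em$lower.CL, upper = em$upper.CL)
  } else {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      L <- design_row(result, grid$group[i], grid$time[i])
      ct <- contrast_test(result, L)
      data.frame(group = grid$group[i], time = grid$time[i],
                 mean = ct$estimate, se = ct$se, df = ct$df2,
                 lower = ct$estimate - stats::qt(.975, ct$df2) * ct$se,
                 upper = ct$estimate + stats::qt(.975, ct$df2) * ct$se)
    })
    do.call(rbind, rows)
  }
}

#' Post-hoc test of change over time within one group
#'
#' Single-df contrast of the 6-month minus baseline change within the named
#' group, using the fitted model's coefficient covariance (Satterthwaite df
#' for mixed fits). The estimate equals the difference of the two
#' model-implied cell means for that group.
#'
#' @param result A `mixed_model_result` from [fit_group_time_model()].
#' @param group Group label present in the fit.
#' @return One-row data frame: `group`, `estimate`, `se`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
posthoc_time_within_group <- function(result, group) {
  if (identical(result$variant, "ancova"))
    stopf("time contrasts are unavailable for the baseline-covariate variant")
  if (!group %in% result$groups) stopf("unknown group '%s'", group)
  L <- design_row(result, group, "t6") - design_row(result, group, "t0")
  cbind(data.frame(group = group), contrast_test(result, L))
}

#' Post-hoc pairwise group contrasts at one timepoint
#'
#' Single-df contrasts between pairs of groups at the given timepoint
#' (baseline `"t0"` or 6 months `"t6"`), with covariates held at their
#' means.
#'
#' @param result A `mixed_model_result`.
#' @param time `"t0"` or `"t6"` (also accepts 0 / 6).
#' @param pairs Optional list of length-2 character vectors; default all
#'   pairs.
#' @return Data frame with one row per pair: `group1`, `group2`, `time`,
#'   `estimate` (group1 minus group2), `se`, `F`, `df1`, `df2`, `p`.
#' @export
posthoc_group_at_time <- function(result, time, pairs = NULL) {
  if (identical(result$variant, "ancova"))
    stopf("cell-mean contrasts are unavailable for the baseline-covariate variant")
  time <- as.character(time)
  time <- c("0" = "t0", "6" = "t6", t0 = "t0", t6 = "t6")[[time]]
  if (is.null(time)) stopf("time must be one of t0/t6/0/6")
  if (is.null(pairs)) {
    cmb <- utils::combn(result$groups, 2, simplify = FALSE)
  } else cmb <- pairs
  rows <- lapply(cmb, function(pr) {
    if (!all(pr %in% result$groups)) stopf("unknown group in pair")
    L <- design_row(result, pr[1], time) - design_row(result, pr[2], time)
    cbind(data.frame(group1 = pr[1], group2 = pr[2], time = time),
          contrast_test(result, L))
  })
  do.call(rbind, rows)
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Linear mixed model for '%s' (%s)\n", x$outcome_name,
              if (x$variant == "lmm") "group * time + covariates + (1 | user)"
              else "ANCOVA variant: 6-month value ~ group + baseline value"))
  if (x$singular) cat("  note: singular / boundary fit (zero random-intercept variance)\n")
  if (x$n_dropped > 0) cat(sprintf("  note: %d rows dropped (missing values)\n", x$n_dropped))
  tt <- x$tests
  tt$F <- round(tt$F, 3); tt$df2 <- round(tt$df2, 1); tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  if (!is.null(x$cell_means)) {
    cat("Model-implied cell means (95% CI):\n")
    cm <- x$cell_means
    cm$mean <- round(cm$mean, 2); cm$se <- round(cm$se, 2)
    cm$lower <- round(cm$lower, 2); cm$upper <- round(cm$upper, 2)
    print(cm[, c("group", "time", "mean", "se", "lower", "upper")],
          row.names = FALSE)
  }
  invisible(x)
}

#' One-way ANOVA from group summary statistics
#'
#' Closed-form between/within F ratio computed from per-group sample sizes,
#' means and standard deviations — useful when only summary-level data are
#' available.
#'
#' @param n,means,sds Numeric vectors of equal length (one entry per group).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Characterize engagement profiles at baseline
#'
#' Compares profiles on demographic and baseline clinical variables:
#' one-way ANOVA for continuous variables, chi-square tests for categorical
#' ones, and Tukey honest-significant-difference pairwise contrasts wherever
#' the omnibus ANOVA is significant at `alpha`. Variables with any group
#' smaller than 2 observations are skipped and reported.
#'
#' @param baseline Data frame with `user_id` and the variables to compare
#'   (one row per user).
#' @param labels Data frame `user_id`, `group` or a named vector
#'   (user -> group).
#' @param continuous,categorical Optional explicit variable lists; by
#'   default numeric columns are treated as continuous and
#'   character/factor/logical columns as categorical.
#' @param alpha Significance level gating the Tukey post-hocs (default
#'   0.05).
#' @return Object of class `characterization_result`: `anova` (data frame
#'   `variable`, `F`, `df1`, `df2`, `p`), `tukey` (named list of Tukey
#'   contrast tables), `chisq` (data frame `variable`, `statistic`, `df`,
#'   `p`), `skipped`.
#' @export
characterize_profiles <- function(baseline, labels, continuous = NULL,
                                  categorical = NULL, alpha = 0.05) {
  if (!is.data.frame(labels))
    labels <- data.frame(user_id = names(labels), group = as.character(labels))
  d <- merge(baseline, labels, by = "user_id")
  d$group <- factor(d$group)
  vars <- setdiff(names(d), c("user_id", "group"))
  if (is.null(continuous))
    continuous <- vars[vapply(d[vars], is.numeric, logical(1))]
  if (is.null(categorical)) categorical <- setdiff(vars, continuous)
  anova_rows <- list(); tukey <- list(); skipped <- character(0)
  for (v in continuous) {
    ok <- !is.na(d[[v]])
    if (any(table(d$group[ok]) < 2)) {
      skipped <- c(skipped, v)
      next
    }
    fit <- stats::aov(d[[v]][ok] ~ d$group[ok])
    s <- summary(fit)[[1]]
    row <- data.frame(variable = v, F = s$`F value`[1], df1 = s$Df[1],
                      df2 = s$Df[2], p = s$`Pr(>F)`[1])
    anova_rows[[v]] <- row
    if (!is.na(row$p) && row$p < alpha) {
      tk <- stats::TukeyHSD(fit)[[1]]
      tukey[[v]] <- data.frame(contrast = rownames(tk), tk, row.names = NULL,
                               check.names = FALSE)
    }
  }
  chisq_rows <- list()
  for (v in categorical) {
    ok <- !is.na(d[[v]])
    tab <- table(d$group[ok], d[[v]][ok])
    if (any(rowSums(tab) < 2) || ncol(tab) < 2) {
      skipped <- c(skipped, v)
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab))
    chisq_rows[[v]] <- data.frame(variable = v, statistic = unname(ct$statistic),
                                  df = unname(ct$parameter), p = ct$p.value)
  }
  structure(list(
    anova = if (length(anova_rows)) do.call(rbind, c(anova_rows, make.row.names = FALSE)) else NULL,
    tukey = tukey,
    chisq = if (length(chisq_rows)) do.call(rbind, c(chisq_rows, make.row.names = FALSE)) else NULL,
    skipped = skipped, alpha = alpha),
    class = "characterization_result")
}

#' @export
print.characterization_result <- function(x, ...) {
  cat("Baseline characterization of profiles\n")
  if (!is.null(x$anova)) {
    cat("One-way ANOVA (continuous variables):\n")
    a <- x$anova
    a$F <- round(a$F, 3); a$p <- signif(a$p, 3)
    print(a, row.names = FALSE)
  }
  if (length(x$tukey) > 0)
    cat("Tukey HSD computed for:", paste(names(x$tukey), collapse = ", "), "\n")
  if (!is.null(x$chisq)) {
    cat("Chi-square (categorical variables):\n")
    ch <- x$chisq
    ch$statistic <- round(ch$statistic, 3); ch$p <- signif(ch$p, 3)
    print(ch, row.names = FALSE)
  }
  if (length(x$skipped) > 0)
    cat("Skipped (a group below n = 2):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
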