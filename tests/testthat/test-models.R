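# Mixed-model outcome analysis and baseline characterization.

fit_toy <- function(shifts, seed = 1, n = c(49, 19, 14), ...) {
  labels <- profile_labels(n = n, groups = names(shifts))
  out <- generate_outcomes(labels, single_effect(shifts), seed = seed)
  fit_group_time_model(out, "psp", ...)
}

test_that("identical groups give near-zero group and interaction F", {
  labels <- data.frame(user_id = sprintf("U%02d", 1:20),
                       group = rep(c("a", "b"), each = 10))
  out <- generate_outcomes(labels, single_effect(c(a = 3, b = 3)), seed = 2)
  # duplicate group a's data into group b so the groups are literally identical
  a_rows <- out[out$group == "a", ]
  b_rows <- a_rows
  b_rows$group <- "b"
  b_rows$user_id <- sub("^U0", "U5", a_rows$user_id)
  dup <- rbind(a_rows, b_rows)
  fit <- fit_group_time_model(dup, "psp", covariates = character(0),
                              cell_means = FALSE)
  tests <- fit$tests
  expect_lt(tests$F[tests$term == "group"], 1e-8)
  expect_lt(tests$F[tests$term == "group:time"], 1e-8)
})

test_that("degenerate zero-noise data recover a literal +5 shift exactly", {
  labels <- data.frame(user_id = sprintf("U%02d", 1:12),
                       group = rep(c("a", "b"), each = 6))
  eff <- list(psp = outcome_effect_spec("psp", 50, c(a = 0, b = 5),
                                        residual_sd = 0,
                                        random_intercept_sd = 0))
  out <- generate_outcomes(labels, eff, seed = 3)
  # zero-variance data legitimately trips lme4's convergence checks
  fit <- suppressWarnings(
    fit_group_time_model(out, "psp", covariates = character(0)))
  ph <- posthoc_time_within_group(fit, "b")
  expect_equal(ph$estimate, 5, tolerance = 1e-8)
  ph0 <- posthoc_time_within_group(fit, "a")
  expect_equal(ph0$estimate, 0, tolerance = 1e-8)
})

test_that("time contrasts equal the difference of model-implied cell means", {
  fit <- fit_toy(c(low_use = 0, maintained_social = 0,
                   maintained_therapy_social = 11), seed = 7)
  for (g in fit$groups) {
    cm <- fit$cell_means
    diff_means <- cm$mean[cm$group == g & cm$time == "t6"] -
      cm$mean[cm$group == g & cm$time == "t0"]
    ph <- posthoc_time_within_group(fit, g)
    expect_equal(ph$estimate, diff_means, tolerance = 1e-6)
  }
  expect_error(posthoc_time_within_group(fit, "nope"), "unknown group")
})

test_that("group contrasts at a timepoint match cell-mean differences", {
  fit <- fit_toy(c(low_use = 0, maintained_social = 0,
                   maintained_therapy_social = 11), seed = 8)
  ph <- posthoc_group_at_time(fit, "t6")
  expect_equal(nrow(ph), 3L)  # all pairs of 3 groups
  cm <- fit$cell_means
  for (i in seq_len(nrow(ph))) {
    d <- cm$mean[cm$group == ph$group1[i] & cm$time == "t6"] -
      cm$mean[cm$group == ph$group2[i] & cm$time == "t6"]
    expect_equal(ph$estimate[i], d, tolerance = 1e-6)
  }
  # numeric timepoints are accepted
  ph0 <- posthoc_group_at_time(fit, 0)
  expect_true(all(ph0$time == "t0"))
})

test_that("with zero random-intercept variance the fit agrees with OLS", {
  labels <- profile_labels(n = c(20, 15, 10))
  shifts <- c(low_use = 0, maintained_social = 2,
              maintained_therapy_social = 8)
  out <- generate_outcomes(labels, single_effect(shifts,
                                                 random_intercept_sd = 0),
                           seed = 5)
  fit <- fit_group_time_model(out, "psp", cell_means = FALSE)
  d <- out
  d$group <- factor(d$group)
  d$time <- factor(ifelse(d$timepoint == 0, "t0", "t6"))
  ols <- stats::lm(value ~ group * time + sex + age + dup_days, data = d)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("F statistics are invariant to group label permutation", {
  shifts <- c(low_use = 1, maintained_social = -2,
              maintained_therapy_social = 9)
  labels <- profile_labels()
  out <- generate_outcomes(labels, single_effect(shifts), seed = 6)
  fit1 <- fit_group_time_model(out, "psp", cell_means = FALSE)
  relabel <- c(low_use = "zz_low", maintained_social = "aa_soc",
               maintained_therapy_social = "mm_both")
  out2 <- out
  out2$group <- unname(relabel[out$group])
  fit2 <- fit_group_time_model(out2, "psp", cell_means = FALSE)
  for (term in c("group", "time", "group:time")) {
    expect_equal(fit1$tests$F[fit1$tests$term == term],
                 fit2$tests$F[fit2$tests$term == term], tolerance = 1e-6)
  }
  # contrasts relabel consistently
  ph1 <- posthoc_time_within_group(fit1, "maintained_therapy_social")
  ph2 <- posthoc_time_within_group(fit2, "mm_both")
  expect_equal(ph1$estimate, ph2$estimate, tolerance = 1e-6)
  expect_equal(ph1$F, ph2$F, tolerance = 1e-4)
})

test_that("post-hoc p values are uniform under the within-group null", {
  shifts <- c(low_use = 0, maintained_social = 0,
              maintained_therapy_social = 0)
  labels <- profile_labels()
  pvals <- vapply(1:120, function(r) {
    out <- generate_outcomes(labels, single_effect(shifts), seed = 5000 + r)
    fit <- fit_group_time_model(out, "psp", cell_means = FALSE)
    posthoc_time_within_group(fit, "low_use")$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("missing covariates drop rows with an accounting", {
  fit0 <- fit_toy(c(low_use = 0, maintained_social = 0,
                    maintained_therapy_social = 5), seed = 9,
                  cell_means = FALSE)
  expect_equal(fit0$n_dropped, 0L)
  labels <- profile_labels(n = c(20, 15, 10))
  out <- generate_outcomes(labels, single_effect(
    c(low_use = 0, maintained_social = 0, maintained_therapy_social = 5)),
    seed = 9)
  out$dup_days[out$user_id == "U001"] <- NA
  fit <- fit_group_time_model(out, "psp", cell_means = FALSE)
  expect_equal(fit$n_dropped, 2L)
})

test_that("the ANCOVA-style baseline-covariate variant fits and reports", {
  fit <- fit_toy(c(low_use = 0, maintained_social = 0,
                   maintained_therapy_social = 11), seed = 10,
                 baseline_covariate = TRUE)
  expect_identical(fit$variant, "ancova")
  expect_true("group" %in% fit$tests$term)
  expect_true("value_t0" %in% fit$tests$term)
  expect_error(posthoc_time_within_group(fit, "low_use"), "unavailable")
})

test_that("summary-statistic ANOVA matches the closed-form ratio", {
  n <- c(49, 19, 14)
  means <- c(11.05, 10.48, 14.36)
  sds <- c(3.55, 3.14, 4.99)
  res <- anova_from_summary(n, means, sds)
  # independent arithmetic
  N <- sum(n); k <- 3
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  expect_equal(res$F, (ssb / (k - 1)) / (ssw / (N - k)), tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 79)
  # and agrees with aov on raw data constructed to those exact summaries
  set.seed(1)
  raw <- unlist(lapply(1:3, function(j) {
    x <- rnorm(n[j])
    means[j] + sds[j] * (x - mean(x)) / stats::sd(x)
  }))
  grp <- factor(rep(1:3, n))
  s <- summary(stats::aov(raw ~ grp))[[1]]
  expect_equal(res$F, s$`F value`[1], tolerance = 1e-8)
})

test_that("baseline characterization runs ANOVA, chi-square and Tukey", {
  set.seed(12)
  labels <- profile_labels(n = c(20, 15, 12))
  baseline <- data.frame(
    user_id = labels$user_id,
    panss_negative = c(rnorm(20, 11, 3.5), rnorm(15, 10.5, 3.1),
                       rnorm(12, 16, 3)),
    age = sample(16:27, 47, replace = TRUE),
    sex = sample(c("male", "female"), 47, replace = TRUE))
  res <- characterize_profiles(baseline, labels)
  expect_s3_class(res, "characterization_result")
  a <- res$anova
  expect_setequal(a$variable, c("panss_negative", "age"))
  pn <- a[a$variable == "panss_negative", ]
  expect_equal(pn$df1, 2)
  expect_equal(pn$df2, 44)
  # Tukey contrasts only where the omnibus is significant
  expect_true("panss_negative" %in% names(res$tukey))
  expect_equal(nrow(res$tukey$panss_negative), 3)
  expect_true("sex" %in% res$chisq$variable)
})

test_that("identical group means give F = 0 and groups below n = 2 are skipped", {
  labels <- data.frame(user_id = sprintf("U%02d", 1:9),
                       group = rep(c("a", "b", "c"), each = 3))
  baseline <- data.frame(user_id = labels$user_id,
                         score = rep(c(1, 2, 3), times = 3))
  res <- characterize_profiles(baseline, labels)
  expect_equal(res$anova$F[res$anova$variable == "score"], 0, tolerance = 1e-12)
  # a variable observed in fewer than 2 members of a group is skipped
  baseline$rare <- c(1, NA, NA, rnorm(6))
  res2 <- characterize_profiles(baseline, labels)
  expect_true("rare" %in% res2$skipped)
})

test_that("chi-square matches hand computation on a 3x2 toy table", {
  labels <- data.frame(user_id = sprintf("U%02d", 1:30),
                       group = rep(c("a", "b", "c"), times = c(12, 10, 8)))
  baseline <- data.frame(
    user_id = labels$user_id,
    vocation = c(rep(c("yes", "no"), c(8, 4)), rep(c("yes", "no"), c(4, 6)),
                 rep(c("yes", "no"), c(5, 3))))
  res <- characterize_profiles(baseline, labels)
  tab <- matrix(c(8, 4, 4, 6, 5, 3), nrow = 3, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_equal(res$chisq$statistic[res$chisq$variable == "vocation"], chi2,
               tolerance = 1e-10)
  expect_equal(res$chisq$df[res$chisq$variable == "vocation"], 2)
})
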