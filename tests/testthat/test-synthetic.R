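# Synthetic cohort generator: archetype machinery, raw-metric emission,
# outcome simulation.

test_that("archetype specs validate their probability structure", {
  p <- matrix(rep(c(.7, .2, .08, .02), each = 22), 22, 4)
  a <- archetype_spec("x", p, p, 0.5)
  expect_s3_class(a, "archetype_spec")
  bad <- p; bad[3, ] <- c(.5, .5, .1, .1)
  expect_error(archetype_spec("x", bad, p, 0.5), "sum to 1")
  expect_error(archetype_spec("x", p[1:10, ], p, 0.5), "22 x 4")
  expect_error(archetype_spec("x", p, p, 1.2), "\\[0, 1\\]")
})

test_that("largest-remainder allocation is deterministic and exact", {
  expect_equal(allocate_archetypes(c(.60, .23, .17), 82), c(49L, 19L, 14L))
  expect_equal(sum(allocate_archetypes(c(.60, .23, .17), 82)), 82L)
  expect_equal(allocate_archetypes(c(.5, .5), 7), c(4L, 3L))
  expect_error(allocate_archetypes(c(.6, .3), 82), "sum to 1")
  # archetype counts in a generated cohort match the quota
  g <- generate_usage_logs(default_archetypes(), n_users = 82, seed = 1)
  counts <- table(g$truth$archetype)[c("low_use", "maintained_social",
                                       "maintained_therapy_social")]
  expect_equal(unname(as.integer(counts)), c(49L, 19L, 14L))
})

test_that("an all-inactive archetype emits all-zero rows", {
  arch <- list(point_mass_archetype("inactive", 1, 1))
  g <- generate_usage_logs(arch, n_users = 3, n_days = 20, seed = 5)
  metrics <- g$log[, usage_variables()]
  expect_true(all(metrics == 0))
  expect_true(all(g$levels$therapy_level == 1))
})

test_that("emitted raw metrics re-categorize to the drawn levels exactly", {
  for (seed in c(2, 77)) {
    g <- generate_usage_logs(default_archetypes(), n_users = 82,
                             n_days = 155, seed = seed)
    cl <- categorize_log(g$log)
    m <- merge(cl[, c("user_id", "day_index", "therapy_level", "social_level")],
               g$levels, by = c("user_id", "day_index"),
               suffixes = c("_recat", "_drawn"))
    expect_equal(nrow(m), 82 * 155)
    expect_identical(m$therapy_level_recat, m$therapy_level_drawn)
    expect_identical(m$social_level_recat, m$social_level_drawn)
  }
})

test_that("identical seeds reproduce the cohort exactly", {
  a <- simulate_cohort(n_users = 12, n_tau = 8, seed = 9)
  b <- simulate_cohort(n_users = 12, n_tau = 8, seed = 9)
  expect_identical(a$usage_log, b$usage_log)
  expect_identical(a$outcomes, b$outcomes)
  c <- simulate_cohort(n_users = 12, n_tau = 8, seed = 10)
  expect_false(identical(a$usage_log, c$usage_log))
})

test_that("per-user substreams make user logs independent of cohort size", {
  small <- generate_usage_logs(default_archetypes(), n_users = 5, seed = 3)
  big <- generate_usage_logs(default_archetypes(), n_users = 9, seed = 3)
  # user 2 is low_use in both cohorts (quota fills archetypes in order)
  expect_identical(small$log[small$log$user_id == "U002", ],
                   big$log[big$log$user_id == "U002", ])
})

test_that("daily level frequencies match the archetype distribution", {
  # chi-square goodness of fit on pooled daily draws in selected weeks
  arch <- default_archetypes()
  g <- generate_usage_logs(arch, n_users = 2000, n_days = 30, seed = 13)
  lv <- merge(g$levels, g$truth, by = "user_id")
  for (week in c(1, 3)) {
    days <- (2 + 7 * (week - 1)):(1 + 7 * week)
    for (a in arch) {
      sub <- lv[lv$archetype == a$name & lv$day_index %in% days, ]
      obs <- tabulate(sub$therapy_level, 4)
      p <- stats::chisq.test(obs, p = a$therapy_level_probs[week, ])$p.value
      expect_gt(p, 0.01)
    }
  }
})

test_that("outcome effect specs validate and cover groups", {
  expect_error(outcome_effect_spec("x", 0, c(a = 1), residual_sd = -1,
                                   random_intercept_sd = 1), "nonnegative")
  expect_error(outcome_effect_spec("x", 0, c(1, 2), 1, 1), "named")
  labels <- data.frame(user_id = c("U1", "U2"), group = c("a", "b"))
  eff <- list(outcome_effect_spec("x", 0, c(a = 1), 1, 1))
  expect_error(generate_outcomes(labels, eff), "no shift for group")
})

test_that("noise-free generation reproduces the planted means exactly", {
  labels <- data.frame(user_id = sprintf("U%02d", 1:6),
                       group = rep(c("a", "b"), each = 3))
  eff <- list(outcome_effect_spec("flat", baseline_mean = 50,
                                  group_time_shift = c(a = 0, b = 0),
                                  residual_sd = 0, random_intercept_sd = 0))
  out <- generate_outcomes(labels, eff, seed = 4)
  expect_true(all(out$value == 50))
  eff2 <- list(outcome_effect_spec("shifted", baseline_mean = 50,
                                   group_time_shift = c(a = 0, b = 5),
                                   residual_sd = 0, random_intercept_sd = 0))
  out2 <- generate_outcomes(labels, eff2, seed = 4)
  expect_true(all(out2$value[out2$group == "b" & out2$timepoint == 6] == 55))
  expect_true(all(out2$value[out2$timepoint == 0] == 50))
})

test_that("covariates respect their stated ranges and are user-constant", {
  out <- generate_outcomes(profile_labels(), default_outcome_effects(
    groups = c("low_use", "maintained_social", "maintained_therapy_social")),
    seed = 8)
  expect_true(all(out$age >= 16 & out$age <= 27))
  expect_true(all(out$sex %in% 0:1))
  expect_true(all(out$dup_days >= 0))
  per_user <- unique(out[, c("user_id", "sex", "age", "dup_days")])
  expect_equal(nrow(per_user), length(unique(out$user_id)))
})

test_that("planted interaction is recovered on average across replicates", {
  labels <- profile_labels()
  shifts <- c(low_use = 0, maintained_social = 0,
              maintained_therapy_social = 11)
  ests <- vapply(1:25, function(r) {
    out <- generate_outcomes(labels, single_effect(shifts), seed = 1000 + r)
    fit <- fit_group_time_model(out, "psp", cell_means = FALSE)
    unname(fit$beta[["groupmaintained_therapy_social:timet6"]])
  }, numeric(1))
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 11), 4 * mc_se + 1e-9)
})

test_that("missingness drops only 6-month rows at the requested rate", {
  cohort <- simulate_cohort(n_users = 40, n_tau = 0, seed = 6,
                            missing_rate = 0.3)
  out <- cohort$outcomes
  n0 <- sum(out$timepoint == 0)
  n6 <- sum(out$timepoint == 6)
  expect_equal(n0, 40 * 4)
  expect_lt(n6, n0)
  expect_gt(n6, n0 * 0.5)
})
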