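# Synthetic cohort generator.
#
# Emulates the data-generating process the pipeline assumes: a cohort of
# intervention users whose daily platform activity follows latent engagement
# archetypes, plus a treatment-as-usual (TAU) arm, with longitudinal clinical
# outcomes carrying planted group-by-time effects. Because the generator
# knows the truth (archetype membership, planted coefficients), clustering
# recovery and mixed-model estimation are testable end to end.

#' Define an engagement archetype
#'
#' An archetype is a latent engagement style: for every week of the
#' trajectory window it gives a probability distribution over the four daily
#' activity levels, separately for the therapy and social dimensions. Each
#' day of a user's log draws its target (therapy, social) level pair from
#' the distributions of the week the day falls in.
#'
#' @param name Archetype label.
#' @param therapy_level_probs,social_level_probs Numeric matrices,
#'   `n_weeks` x 4: row `w` is the probability distribution over daily
#'   levels 1-4 in week `w`. Rows must sum to 1 (tolerance 1e-9).
#' @param prevalence Fraction of the cohort belonging to this archetype.
#' @param n_weeks Number of weekly rows expected (default 22).
#' @return Object of class `archetype_spec`.
#' @seealso [default_archetypes()]
#' @export
archetype_spec <- function(name, therapy_level_probs, social_level_probs,
                           prevalence, n_weeks = 22L) {
  for (nm in c("therapy_level_probs", "social_level_probs")) {
    p <- get(nm)
    if (!is.matrix(p) || nrow(p) != n_weeks || ncol(p) != 4)
      stopf("%s must be a %d x 4 matrix", nm, n_weeks)
    if (any(p < 0)) stopf("%s has negative entries", nm)
    if (any(abs(rowSums(p) - 1) > 1e-9))
      stopf("%s rows must sum to 1 (tolerance 1e-9)", nm)
  }
  if (prevalence < 0 || prevalence > 1) stopf("prevalence must be in [0, 1]")
  structure(list(name = name, therapy_level_probs = therapy_level_probs,
                 social_level_probs = social_level_probs,
                 prevalence = prevalence, n_weeks = as.integer(n_weeks)),
            class = "archetype_spec")
}

# Build a n_weeks x 4 probability matrix from per-phase rows:
# phases is a list of list(weeks = integer vector, probs = length-4 vector).
phase_probs <- function(phases, n_weeks = 22L) {
  m <- matrix(NA_real_, n_weeks, 4)
  for (ph in phases) m[ph$weeks, ] <- matrix(ph$probs, length(ph$weeks), 4, byrow = TRUE)
  if (anyNA(m)) stopf("phases do not cover all %d weeks", n_weeks)
  m / rowSums(m)
}

#' Default engagement archetypes
#'
#' Three archetypes emulating the qualitative trajectory shapes commonly
#' seen in long-running digital interventions, at prevalences 0.60 / 0.23 /
#' 0.17:
#' \describe{
#'   \item{`low_use`}{initial exploration in the first two weeks, then
#'     near-total disengagement on both dimensions.}
#'   \item{`maintained_social`}{sustained moderate-to-active social
#'     networking throughout, while therapy use decays to passive/inactive.}
#'   \item{`maintained_therapy_social`}{variable but sustained activity on
#'     both dimensions, tapering only in the final weeks.}
#' }
#' The weekly level distributions are chosen so that the implied weekly-score
#' centroids of the three archetypes are well separated (the maintained
#' profiles differ from each other by more than 1.5 levels on the therapy
#' dimension for most of the window, and from `low_use` on both dimensions).
#'
#' @param n_weeks Trajectory length in weeks (default 22).
#' @return List of three `archetype_spec` objects.
#' @export
default_archetypes <- function(n_weeks = 22L) {
  wk <- function(a, b) seq(a, min(b, n_weeks))
  low_therapy <- phase_probs(list(
    list(weeks = 1, probs = c(.20, .20, .35, .25)),
    list(weeks = 2, probs = c(.55, .20, .15, .10)),
    list(weeks = 3, probs = c(.85, .09, .04, .02)),
    list(weeks = wk(4, n_weeks), probs = c(.97, .02, .008, .002))), n_weeks)
  low_social <- phase_probs(list(
    list(weeks = 1, probs = c(.15, .15, .30, .40)),
    list(weeks = 2, probs = c(.50, .20, .15, .15)),
    list(weeks = 3, probs = c(.85, .08, .05, .02)),
    list(weeks = wk(4, n_weeks), probs = c(.97, .015, .01, .005))), n_weeks)
  ms_therapy <- phase_probs(list(
    list(weeks = 1, probs = c(.25, .20, .30, .25)),
    list(weeks = 2, probs = c(.45, .25, .20, .10)),
    list(weeks = wk(3, n_weeks), probs = c(.78, .17, .04, .01))), n_weeks)
  ms_social <- phase_probs(list(
    list(weeks = wk(1, 2), probs = c(.20, .10, .30, .40)),
    list(weeks = wk(3, 18), probs = c(.40, .12, .28, .20)),
    list(weeks = wk(19, n_weeks), probs = c(.55, .15, .20, .10))), n_weeks)
  mts_therapy <- phase_probs(list(
    list(weeks = wk(1, 2), probs = c(.20, .15, .30, .35)),
    list(weeks = wk(3, 18), probs = c(.22, .10, .28, .40)),
    list(weeks = wk(19, n_weeks), probs = c(.60, .18, .13, .09))), n_weeks)
  mts_social <- phase_probs(list(
    list(weeks = wk(1, 2), probs = c(.20, .12, .28, .40)),
    list(weeks = wk(3, 18), probs = c(.30, .12, .30, .28)),
    list(weeks = wk(19, n_weeks), probs = c(.58, .14, .16, .12))), n_weeks)
  list(
    archetype_spec("low_use", low_therapy, low_social, 0.60, n_weeks),
    archetype_spec("maintained_social", ms_therapy, ms_social, 0.23, n_weeks),
    archetype_spec("maintained_therapy_social", mts_therapy, mts_social, 0.17,
                   n_weeks))
}

#' Benchmark archetypes with mutually well-separated centroids
#'
#' Three archetypes built for planted-recovery experiments: unlike
#' [default_archetypes()] — which emulates realistic published-style
#' trajectory shapes where two maintained profiles are closer to each other
#' than to the disengaged mass, so validity indices can legitimately favour
#' merging them — this preset places the three weekly-score centroids far
#' apart in every pairwise comparison (every pair differs by at least 1.5
#' levels on well over 8 weeks) with crisp weekly level distributions, so a
#' correct selection procedure should recover exactly three clusters.
#'
#' \describe{
#'   \item{`disengaged`}{near-total inactivity on both dimensions.}
#'   \item{`social_only`}{consistently active social networking, passive
#'     therapy.}
#'   \item{`dual_engaged`}{consistently high therapy engagement with
#'     passive-to-moderate social use.}
#' }
#'
#' @param prevalences Numeric vector of three prevalences summing to 1
#'   (default `c(0.60, 0.23, 0.17)`).
#' @param n_weeks Trajectory length (default 22).
#' @return List of three `archetype_spec` objects.
#' @export
separated_archetypes <- function(prevalences = c(0.60, 0.23, 0.17),
                                 n_weeks = 22L) {
  stopifnot(length(prevalences) == 3)
  flat <- function(probs) phase_probs(list(
    list(weeks = seq_len(n_weeks), probs = probs)), n_weeks)
  quiet <- flat(c(.96, .02, .01, .01))
  high <- flat(c(.05, .05, .10, .80))
  passive <- flat(c(.80, .15, .04, .01))
  moderate <- flat(c(.30, .60, .08, .02))
  list(
    archetype_spec("disengaged", quiet, quiet, prevalences[1], n_weeks),
    archetype_spec("social_only", passive, high, prevalences[2], n_weeks),
    archetype_spec("dual_engaged", high, moderate, prevalences[3], n_weeks))
}

#' Deterministic largest-remainder allocation of users to archetypes
#'
#' Allocates `n` users across archetype prevalences by the largest-remainder
#' quota method, so that cohort composition is deterministic (no i.i.d.
#' sampling noise) and stable across runs. Ties in the fractional remainder
#' are broken by archetype order.
#'
#' @param prevalences Numeric vector summing to 1.
#' @param n Number of users.
#' @return Integer vector of counts summing to `n`.
#' @export
allocate_archetypes <- function(prevalences, n) {
  if (abs(sum(prevalences) - 1) > 1e-6)
    stopf("archetype prevalences must sum to 1 (got %.6f)", sum(prevalences))
  quota <- prevalences * n
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Emit raw therapy-side metrics consistent with target levels (vectorized
# over days). Emission is minimally sufficient for the target level plus
# optional extras that cannot raise the level (passive visits at levels >= 2,
# extra units at level 4, where the condition is closed under increments).
emit_therapy <- function(lv) {
  n <- length(lv)
  steps <- integer(n); actions <- integer(n)
  vis_th <- integer(n); vis_sug <- integer(n)
  i2 <- which(lv == 2)
  if (length(i2)) {
    pick <- sample.int(3, length(i2), replace = TRUE)  # therapy / suggested / both
    vis_th[i2] <- as.integer(pick != 2)
    vis_sug[i2] <- as.integer(pick != 1)
  }
  i3 <- which(lv == 3)
  if (length(i3)) {
    step_side <- stats::runif(length(i3)) < 0.5
    steps[i3] <- as.integer(step_side)
    actions[i3] <- as.integer(!step_side)
  }
  i4 <- which(lv == 4)
  if (length(i4)) {
    pattern <- sample.int(3, length(i4), replace = TRUE)  # (2,0) / (0,2) / (1,1)
    steps[i4] <- c(2L, 0L, 1L)[pattern] + stats::rpois(length(i4), 0.5)
    actions[i4] <- c(0L, 2L, 1L)[pattern] + stats::rpois(length(i4), 0.5)
    # keep the defining pattern intact when extras land on a zero slot
    steps[i4][pattern == 2] <- 0L
    actions[i4][pattern == 1] <- 0L
  }
  i_active <- which(lv >= 3)
  if (length(i_active)) {  # active days may also browse
    vis_th[i_active] <- as.integer(stats::runif(length(i_active)) < 0.5)
    vis_sug[i_active] <- as.integer(stats::runif(length(i_active)) < 0.25)
  }
  data.frame(steps_started = steps, actions_done = actions,
             visited_suggested_content = vis_sug, visited_therapy = vis_th)
}

emit_social <- function(lv) {
  n <- length(lv)
  posts <- integer(n); comments <- integer(n); tio <- integer(n)
  likes <- integer(n); reacts <- integer(n)
  vis <- matrix(0L, n, 4,
                dimnames = list(NULL, c("visited_messages", "visited_notifications",
                                        "visited_newsfeed", "visited_talk_it_out")))
  i2 <- which(lv == 2)
  if (length(i2)) {
    main <- sample.int(4, length(i2), replace = TRUE)
    vis[cbind(i2, main)] <- 1L
    extra <- matrix(stats::runif(length(i2) * 4) < 0.3, length(i2), 4)
    vis[i2, ] <- pmax(vis[i2, , drop = FALSE], extra * 1L)
  }
  i3 <- which(lv == 3)
  if (length(i3)) {
    likes[i3] <- stats::rpois(length(i3), 0.7)
    reacts[i3] <- stats::rpois(length(i3), 0.5)
    none <- likes[i3] + reacts[i3] == 0
    likes[i3][none] <- 1L
  }
  i4 <- which(lv == 4)
  if (length(i4)) {
    kind <- sample.int(3, length(i4), replace = TRUE)  # post / comment / forum
    posts[i4] <- as.integer(kind == 1) + stats::rpois(length(i4), 0.3)
    comments[i4] <- as.integer(kind == 2) + stats::rpois(length(i4), 0.3)
    tio[i4] <- as.integer(kind == 3)
    likes[i4] <- stats::rpois(length(i4), 0.5)
    reacts[i4] <- stats::rpois(length(i4), 0.3)
  }
  i_act <- which(lv >= 3)
  if (length(i_act)) {
    browse <- matrix(stats::runif(length(i_act) * 4) < 0.4, length(i_act), 4)
    vis[i_act, ] <- pmax(vis[i_act, , drop = FALSE], browse * 1L)
  }
  cbind(data.frame(newsfeed_posts = posts, newsfeed_comments = comments,
                   talk_it_out_posts = tio, likes_made = likes,
                   reactions_made = reacts),
        as.data.frame(vis))
}

draw_levels <- function(probs, week_of_day) {
  cum <- t(apply(probs, 1, cumsum))[week_of_day, , drop = FALSE]
  u <- stats::runif(length(week_of_day))
  1L + as.integer(u > cum[, 1]) + as.integer(u > cum[, 2]) + as.integer(u > cum[, 3])
}

#' Generate synthetic daily usage logs with known archetype structure
#'
#' Users are allocated to archetypes by deterministic largest-remainder
#' quota ([allocate_archetypes()]). For each user-day a target (therapy,
#' social) activity-level pair is drawn from the user's archetype
#' distribution for the week the day falls in, and raw metrics consistent
#' with that pair under the hierarchical categorization rules are emitted,
#' so that re-categorizing the log reproduces the drawn levels exactly.
#' Day 1 is each user's induction day: it is emitted like any other day but
#' is excluded by downstream trajectory building. A single global seed fans
#' out to independent per-user substreams, so each user's log is stable
#' regardless of cohort size or ordering.
#'
#' @param archetypes List of [archetype_spec()] objects; prevalences must
#'   sum to 1.
#' @param n_users Number of intervention users (default 82).
#' @param n_days Days of trial involvement per user (default 155; at least
#'   155 is needed to fill the default 22-week window).
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated user ids.
#' @return List with `log` (usage-log data frame: `user_id`, `day_index`,
#'   13 metric columns; one row per user-day including all-zero inactive
#'   days), `truth` (data frame `user_id`, `archetype`) and `levels` (data
#'   frame of the drawn per-day level pairs, the generative ground truth).
#' @export
generate_usage_logs <- function(archetypes, n_users = 82L, n_days = 155L,
                                seed = 1L, id_prefix = "U") {
  if (n_users <= 0 || n_days <= 0) stopf("n_users and n_days must be positive")
  prev <- vapply(archetypes, function(a) a$prevalence, numeric(1))
  counts <- allocate_archetypes(prev, n_users)
  n_weeks <- archetypes[[1]]$n_weeks
  arch_names <- vapply(archetypes, function(a) a$name, character(1))
  users <- sprintf("%s%03d", id_prefix, seq_len(n_users))
  membership <- rep(arch_names, counts)
  days <- seq_len(n_days)
  # day 1 (induction) draws from week 1; days past the window reuse the
  # final week's distribution
  week_of_day <- pmin(pmax((days - 2L) %/% 7L + 1L, 1L), n_weeks)
  logs <- vector("list", n_users)
  lvls <- vector("list", n_users)
  for (i in seq_len(n_users)) {
    a <- archetypes[[match(membership[i], arch_names)]]
    set.seed(fan_out_seed(seed, i))
    t_lv <- draw_levels(a$therapy_level_probs, week_of_day)
    s_lv <- draw_levels(a$social_level_probs, week_of_day)
    logs[[i]] <- cbind(
      data.frame(user_id = users[i], day_index = days),
      emit_therapy(t_lv), emit_social(s_lv))
    lvls[[i]] <- data.frame(user_id = users[i], day_index = days,
                            therapy_level = t_lv, social_level = s_lv)
  }
  log <- do.call(rbind, logs)
  log <- log[, c("user_id", "day_index", usage_variables())]
  rownames(log) <- NULL
  list(log = log,
       truth = data.frame(user_id = users, archetype = membership),
       levels = do.call(rbind, lvls))
}

#' Define a planted outcome effect
#'
#' Specifies the generative model for one clinical outcome:
#' `value(u, t) = baseline_mean + b_u + shift[group(u)] * 1(t = 6mo) +`
#' covariate contributions `+ e`, with per-user random intercept
#' `b_u ~ N(0, random_intercept_sd^2)` and residual
#' `e ~ N(0, residual_sd^2)`.
#'
#' @param outcome_name Outcome label (e.g. `"psp"`).
#' @param baseline_mean Mean at baseline, score units.
#' @param group_time_shift Named numeric: change from baseline to 6 months
#'   per group label. Must cover every group label the generator is asked
#'   about.
#' @param residual_sd,random_intercept_sd Nonnegative standard deviations.
#' @param baseline_sd Optional descriptive marginal SD at baseline (defaults
#'   to `sqrt(random_intercept_sd^2 + residual_sd^2)`); not used in
#'   generation, retained for reporting.
#' @param covariate_coefs Named numeric contributions of `sex` (0/1),
#'   `age` (years, centred at 21) and `dup_days` (log days untreated
#'   psychosis, centred at log 60). Default all zero.
#' @return Object of class `outcome_effect_spec`.
#' @export
outcome_effect_spec <- function(outcome_name, baseline_mean, group_time_shift,
                                residual_sd, random_intercept_sd,
                                baseline_sd = NULL,
                                covariate_coefs = c(sex = 0, age = 0, dup_days = 0)) {
  if (residual_sd < 0 || random_intercept_sd < 0 ||
      (!is.null(baseline_sd) && baseline_sd < 0))
    stopf("standard deviations must be nonnegative")
  if (is.null(names(group_time_shift)))
    stopf("group_time_shift must be a named vector (group -> shift)")
  cc <- c(sex = 0, age = 0, dup_days = 0)
  cc[names(covariate_coefs)] <- covariate_coefs
  structure(list(outcome_name = outcome_name, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd %||%
                   sqrt(residual_sd^2 + random_intercept_sd^2),
                 group_time_shift = group_time_shift,
                 residual_sd = residual_sd,
                 random_intercept_sd = random_intercept_sd,
                 covariate_coefs = cc),
            class = "outcome_effect_spec")
}

#' Default planted outcome effects
#'
#' Effect specifications for four trial outcomes — social functioning (PSP),
#' overall psychiatric symptom severity (PANSS total), negative symptoms
#' (PANSS negative) and anxiety (DASS anxiety) — with baseline-to-6-month
#' shifts per engagement profile and TAU chosen to mirror the magnitudes a
#' maintained-engagement profile would plausibly show (e.g. PSP improving by
#' 11 points for the maintained therapy-and-social profile while other
#' groups change little). Variance components reflect typical instrument
#' SDs.
#'
#' @param groups Character vector of group labels the shifts must cover.
#' @return Named list of `outcome_effect_spec` objects.
#' @export
default_outcome_effects <- function(groups = c("low_use", "maintained_social",
                                               "maintained_therapy_social", "TAU")) {
  shifts <- function(low, ms, mts, tau)
    c(low_use = low, maintained_social = ms,
      maintained_therapy_social = mts, TAU = tau)[groups]
  list(
    psp = outcome_effect_spec(
      "psp", baseline_mean = 66,
      group_time_shift = shifts(1.55, -3.06, 11.0, 1.70),
      residual_sd = 9, random_intercept_sd = 9),
    panss_total = outcome_effect_spec(
      "panss_total", baseline_mean = 45,
      group_time_shift = shifts(-0.19, 3.11, -7.18, 1.46),
      residual_sd = 7.5, random_intercept_sd = 10),
    panss_negative = outcome_effect_spec(
      "panss_negative", baseline_mean = 11,
      group_time_shift = shifts(-0.71, -0.69, -4.34, -0.36),
      residual_sd = 2.8, random_intercept_sd = 2.8),
    dass_anxiety = outcome_effect_spec(
      "dass_anxiety", baseline_mean = 11,
      group_time_shift = shifts(-0.12, 3.79, -0.73, -3.35),
      residual_sd = 7, random_intercept_sd = 6.5))
}

#' Generate longitudinal outcomes with planted group-by-time effects
#'
#' Simulates the two-timepoint outcome process the mixed models assume:
#' per-user random intercept, fixed group/time/interaction structure, and
#' user-level covariates (sex ~ Bernoulli(0.5); age ~ discrete uniform
#' 16-27 years; days of untreated psychosis ~ log-normal, median 60 days).
#' Covariates are constant within user across outcomes and timepoints.
#'
#' @param labels Data frame `user_id`, `group` covering every user
#'   (intervention profiles and TAU).
#' @param effects List of [outcome_effect_spec()] objects; each
#'   `group_time_shift` must name every group present in `labels`.
#' @param seed Integer seed (fans out per user).
#' @param missing_rate Fraction of 6-month rows dropped completely at
#'   random (default 0).
#' @return Long-format data frame: `user_id`, `group`, `arm`
#'   (`intervention`/`TAU`), `timepoint` (0 or 6), `outcome_name`, `value`,
#'   `sex`, `age`, `dup_days`.
#' @export
generate_outcomes <- function(labels, effects, seed = 1L, missing_rate = 0) {
  stopifnot(all(c("user_id", "group") %in% names(labels)))
  groups <- unique(as.character(labels$group))
  for (eff in effects) {
    unknown <- setdiff(groups, names(eff$group_time_shift))
    if (length(unknown) > 0)
      stopf("effect '%s' has no shift for group(s): %s",
            eff$outcome_name, paste(unknown, collapse = ", "))
  }
  labels <- labels[order(as.character(labels$user_id)), ]
  n <- nrow(labels)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(fan_out_seed(seed, i) %% 2147483647)
    sex <- stats::rbinom(1, 1, 0.5)
    age <- sample(16:27, 1)
    dup <- round(stats::rlnorm(1, meanlog = log(60), sdlog = 1))
    g <- as.character(labels$group[i])
    rows <- lapply(effects, function(eff) {
      b_u <- stats::rnorm(1, 0, eff$random_intercept_sd)
      eps <- stats::rnorm(2, 0, eff$residual_sd)
      cov_part <- eff$covariate_coefs[["sex"]] * sex +
        eff$covariate_coefs[["age"]] * (age - 21) +
        eff$covariate_coefs[["dup_days"]] * (log(dup) - log(60))
      value <- eff$baseline_mean + b_u + cov_part +
        c(0, eff$group_time_shift[[g]]) + eps
      data.frame(user_id = labels$user_id[i], group = g,
                 arm = if (g == "TAU") "TAU" else "intervention",
                 timepoint = c(0L, 6L), outcome_name = eff$outcome_name,
                 value = value, sex = sex, age = age, dup_days = dup)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (missing_rate > 0) {
    set.seed(fan_out_seed(seed, 0))
    at6 <- which(res$timepoint == 6L)
    drop <- at6[stats::runif(length(at6)) < missing_rate]
    if (length(drop) > 0) res <- res[-drop, ]
  }
  res
}

#' Simulate a complete synthetic cohort
#'
#' Bundles [generate_usage_logs()] and [generate_outcomes()]: an
#' intervention arm with archetype-structured usage logs and a TAU arm with
#' outcomes only. The returned truth tables make clustering recovery and
#' effect-estimation experiments self-validating.
#'
#' @inheritParams generate_usage_logs
#' @param effects List of [outcome_effect_spec()]; shifts must cover the
#'   archetype names plus `"TAU"`.
#' @param n_tau Number of TAU participants (default 84).
#' @param missing_rate Passed to [generate_outcomes()].
#' @return Object of class `synthetic_cohort`: list with `usage_log`,
#'   `outcomes`, `truth` (intervention user -> archetype), `levels` (drawn
#'   daily levels) and the generating `seed`.
#' @export
simulate_cohort <- function(archetypes = default_archetypes(),
                            effects = default_outcome_effects(),
                            n_users = 82L, n_tau = 84L, n_days = 155L,
                            seed = 1L, missing_rate = 0) {
  usage <- generate_usage_logs(archetypes, n_users = n_users, n_days = n_days,
                               seed = seed)
  labels <- rbind(
    data.frame(user_id = usage$truth$user_id, group = usage$truth$archetype),
    if (n_tau > 0)
      data.frame(user_id = sprintf("T%03d", seq_len(n_tau)), group = "TAU"))
  outcomes <- generate_outcomes(labels, effects,
                                seed = fan_out_seed(seed, 999983),
                                missing_rate = missing_rate)
  structure(list(usage_log = usage$log, outcomes = outcomes,
                 truth = usage$truth, levels = usage$levels, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (seed %s)\n", format(x$seed)))
  cat(sprintf("  intervention users: %d (%d user-days logged)\n",
              nrow(x$truth), nrow(x$usage_log)))
  cat("  archetypes: ",
      paste(sprintf("%s=%d", names(table(x$truth$archetype)),
                    table(x$truth$archetype)), collapse = ", "), "\n", sep = "")
  cat(sprintf("  outcome rows: %d (%d outcomes, %d groups)\n",
              nrow(x$outcomes), length(unique(x$outcomes$outcome_name)),
              length(unique(x$outcomes$group))))
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Writes the usage log, long-format outcomes and truth tables using the
#' pipeline's CSV dialect (optional `#`-prefixed provenance header).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param header Optional comment lines.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(usage_log = file.path(dir, "usage_log.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             truth = file.path(dir, "truth.csv"))
  tables <- list(cohort$usage_log, cohort$outcomes, cohort$truth)
  for (i in seq_along(paths)) {
    con <- file(paths[[i]], "w")
    if (length(header) > 0) writeLines(paste("#", header), con)
    utils::write.csv(tables[[i]], con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}
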