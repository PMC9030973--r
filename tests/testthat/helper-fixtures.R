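# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use naive loops/enumeration and share no code
# with the package implementations they check.

zero_day <- function(user_id = "U1", day_index = 2L) {
  row <- as.list(stats::setNames(rep(0, length(usage_variables())),
                                 usage_variables()))
  c(list(user_id = user_id, day_index = day_index), row)
}

make_day <- function(..., user_id = "U1", day_index = 2L) {
  row <- zero_day(user_id, day_index)
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row)
}

make_log <- function(...) do.call(rbind, list(...))

# --- brute-force oracles -------------------------------------------------

bf_dist <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

bf_centroids <- function(X, labels) {
  ks <- sort(unique(labels))
  C <- matrix(0, length(ks), ncol(X))
  for (j in seq_along(ks)) C[j, ] <- colMeans(X[labels == ks[j], , drop = FALSE])
  C
}

bf_calinski_harabasz <- function(X, labels) {
  C <- bf_centroids(X, labels)
  ks <- sort(unique(labels))
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (j in seq_along(ks)) {
    members <- which(labels == ks[j])
    for (i in members) W <- W + bf_dist(X[i, ], C[j, ])^2
    B <- B + length(members) * bf_dist(C[j, ], grand)^2
  }
  n <- nrow(X); k <- length(ks)
  (B / (k - 1)) / (W / (n - k))
}

bf_ray_turi <- function(X, labels) {
  C <- bf_centroids(X, labels)
  ks <- sort(unique(labels))
  W <- 0
  for (j in seq_along(ks))
    for (i in which(labels == ks[j])) W <- W + bf_dist(X[i, ], C[j, ])^2
  min_sep <- Inf
  for (a in seq_along(ks)) for (b in seq_along(ks))
    if (a < b) min_sep <- min(min_sep, bf_dist(C[a, ], C[b, ])^2)
  (W / nrow(X)) / min_sep
}

bf_davies_bouldin <- function(X, labels) {
  C <- bf_centroids(X, labels)
  ks <- sort(unique(labels))
  s <- vapply(seq_along(ks), function(j) {
    members <- which(labels == ks[j])
    mean(vapply(members, function(i) bf_dist(X[i, ], C[j, ]), numeric(1)))
  }, numeric(1))
  total <- 0
  for (a in seq_along(ks)) {
    worst <- -Inf
    for (b in seq_along(ks)) if (a != b)
      worst <- max(worst, (s[a] + s[b]) / bf_dist(C[a, ], C[b, ]))
    total <- total + worst
  }
  total / length(ks)
}

bf_rand <- function(a, b) {
  n <- length(a)
  agree <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / pairs
}

# Weekly-score trajectories drawn directly (no usage-log emission): two
# well-separated planted clusters for quick clustering tests.
planted_blobs <- function(n1 = 10, n2 = 10, n_weeks = 22, jitter = 0.3,
                          seed = 42) {
  set.seed(seed)
  base1 <- rep(1, 2 * n_weeks)
  base2 <- rep(4, 2 * n_weeks)
  X <- rbind(
    t(replicate(n1, pmin(4, pmax(1, base1 + rnorm(2 * n_weeks, 0, jitter))))),
    t(replicate(n2, pmin(4, pmax(1, base2 + rnorm(2 * n_weeks, 0, jitter))))))
  rownames(X) <- sprintf("U%02d", seq_len(n1 + n2))
  list(X = X, truth = rep(1:2, c(n1, n2)))
}

# Archetype with all probability mass on one level for every week.
point_mass_archetype <- function(name, therapy_level, social_level,
                                 prevalence = 1, n_weeks = 22) {
  pm <- function(lv) {
    p <- matrix(0, n_weeks, 4)
    p[, lv] <- 1
    p
  }
  archetype_spec(name, pm(therapy_level), pm(social_level), prevalence,
                 n_weeks)
}

# Fixed three-profile label table at the published-style sizes (49, 19, 14).
profile_labels <- function(n = c(49, 19, 14),
                           groups = c("low_use", "maintained_social",
                                      "maintained_therapy_social")) {
  data.frame(user_id = sprintf("U%03d", seq_len(sum(n))),
             group = rep(groups, n))
}

# One-outcome effect list with configurable shifts.
single_effect <- function(shifts, residual_sd = 9, random_intercept_sd = 9) {
  list(psp = outcome_effect_spec("psp", baseline_mean = 66,
                                 group_time_shift = shifts,
                                 residual_sd = residual_sd,
                                 random_intercept_sd = random_intercept_sd))
}
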