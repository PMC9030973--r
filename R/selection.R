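# Model selection across candidate cluster counts.

#' Fit, validate and select a cluster solution over a range of k
#'
#' Fits [joint_kmeans()] for each candidate `k`, computes the three validity
#' indices and (optionally) the resampling stability, applies the
#' small-cluster exclusion rule, and ranks the surviving candidates by
#' majority vote over the indices (Calinski-Harabasz high, Ray-Turi low,
#' Davies-Bouldin low). Vote ties are broken by higher mean Rand stability,
#' then by the smaller `k` (parsimony). The procedure never silently
#' overrides: if every candidate is excluded the result says so and no
#' solution is chosen, and the full candidate table (with exclusion reasons
#' and votes) is always returned so a user can override on interpretability
#' grounds.
#'
#' @param x A `trajectory_matrix` or numeric matrix.
#' @param k_range Candidate cluster counts (default `2:4`).
#' @param min_cluster_size Exclusion threshold: a count when `>= 1`, a
#'   fraction of the sample when `< 1` (default 0.15).
#' @param n_restarts Restarts per fit (default 100).
#' @param n_resamples Stability resamples per candidate (default 100; 0
#'   skips stability, leaving ties broken by parsimony alone).
#' @param frac Stability subsample fraction.
#' @param seed Optional integer seed; candidate fits get deterministic
#'   derived seeds.
#' @return Object of class `solution_selection`: `chosen` (the winning
#'   `cluster_solution`, or `NULL` when no candidate is admissible), `k`
#'   (chosen k or `NA`), `candidates` (data frame with indices, sizes,
#'   exclusion status, stability and votes), `solutions` (all fitted
#'   solutions), `stability` (list of `stability_report`s), `rationale`
#'   (character lines).
#' @export
select_solution <- function(x, k_range = 2:4, min_cluster_size = 0.15,
                            n_restarts = 100L, n_resamples = 100L,
                            frac = 0.8, seed = NULL) {
  if (length(k_range) == 0) stopf("k_range must be nonempty")
  X <- coerce_traj(x)
  solutions <- list()
  stab <- list()
  rows <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit_seed <- if (is.null(seed)) NULL else fan_out_seed(seed, i)
    sol <- joint_kmeans(X, k, n_restarts = n_restarts, seed = fit_seed)
    solutions[[as.character(k)]] <- sol
    row <- fit_indices(X, sol, min_cluster_size)
    if (n_resamples > 0) {
      st <- stability(X, k, n_resamples = n_resamples, frac = frac,
                      seed = if (is.null(fit_seed)) NULL else fan_out_seed(fit_seed, 1),
                      reference = sol)
      stab[[as.character(k)]] <- st
      row$mean_rand <- st$mean_rand
      row$mean_ari <- st$mean_ari
    } else {
      row$mean_rand <- NA_real_
      row$mean_ari <- NA_real_
    }
    rows[[i]] <- row
  }
  cand <- do.call(rbind, rows)
  cand$votes <- 0L
  admissible <- which(!cand$excluded)
  rationale <- character(0)
  chosen_k <- NA_integer_
  if (length(admissible) > 0) {
    adm <- cand[admissible, ]
    voters <- c(calinski_harabasz = +1, ray_turi = -1, davies_bouldin = -1)
    for (v in names(voters)) {
      best <- if (voters[[v]] > 0) which.max(adm[[v]]) else which.min(adm[[v]])
      cand$votes[admissible[best]] <- cand$votes[admissible[best]] + 1L
      rationale <- c(rationale,
                     sprintf("%s favours k = %d", v, adm$k[best]))
    }
    top <- admissible[cand$votes[admissible] == max(cand$votes[admissible])]
    if (length(top) > 1) {
      rationale <- c(rationale, "index vote tied; breaking by mean Rand stability")
      mr <- cand$mean_rand[top]
      if (!all(is.na(mr))) top <- top[which(mr == max(mr, na.rm = TRUE))]
      if (length(top) > 1) {
        rationale <- c(rationale, "stability tied; preferring smaller k")
        top <- top[which.min(cand$k[top])]
      }
    }
    chosen_k <- cand$k[top[1]]
    rationale <- c(rationale, sprintf("selected k = %d by majority vote", chosen_k))
  } else {
    rationale <- c(rationale,
                   "no admissible solution: every candidate has a cluster below the size threshold")
  }
  excluded_k <- cand$k[cand$excluded]
  if (length(excluded_k) > 0)
    rationale <- c(sprintf("excluded k = %s (small cluster)",
                           paste(excluded_k, collapse = ", ")), rationale)
  structure(list(
    chosen = if (!is.na(chosen_k)) solutions[[as.character(chosen_k)]] else NULL,
    k = chosen_k, candidates = cand, solutions = solutions,
    stability = stab, rationale = rationale,
    min_cluster_size = min_cluster_size),
    class = "solution_selection")
}

#' @export
print.solution_selection <- function(x, ...) {
  cat("Cluster-solution selection\n")
  tab <- x$candidates
  tab$calinski_harabasz <- round(tab$calinski_harabasz, 2)
  tab$ray_turi <- round(tab$ray_turi, 3)
  tab$davies_bouldin <- round(tab$davies_bouldin, 3)
  if (!all(is.na(tab$mean_rand))) tab$mean_rand <- round(tab$mean_rand, 3)
  print(tab[, setdiff(names(tab), c("mean_ari", "reason"))], row.names = FALSE)
  for (line in x$rationale) cat(" -", line, "\n")
  if (is.na(x$k)) cat("No admissible solution.\n")
  invisible(x)
}
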