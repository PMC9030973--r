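# Resampling stability of a clustering solution.

#' Rand-index stability under user resampling
#'
#' Internal validation of a k-cluster solution: the full-sample solution is
#' compared against solutions refitted on repeated subsamples of the users
#' (default 80% drawn without replacement), using the Rand index computed on
#' the overlap. Scores near 1 indicate that users tend to be co-assigned the
#' same way regardless of which subsample they appear in. The adjusted Rand
#' index is logged alongside the raw Rand index.
#'
#' @param x A `trajectory_matrix` or numeric matrix.
#' @param k Number of clusters.
#' @param n_resamples Number of resamples (default 100).
#' @param frac Subsample fraction in `(0, 1]` (default 0.8).
#' @param seed Optional integer seed.
#' @param n_restarts Restarts for each refit (default 20; the refits need
#'   fewer restarts than the reference fit because the subsampled problems
#'   are smaller).
#' @param reference Optional precomputed full-sample `cluster_solution`
#'   (refitted with 100 restarts when omitted).
#' @return Object of class `stability_report`: `k`, `rand_scores`,
#'   `mean_rand`, `ari_scores`, `mean_ari`.
#' @export
stability <- function(x, k, n_resamples = 100L, frac = 0.8, seed = NULL,
                      n_restarts = 20L, reference = NULL) {
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  X <- coerce_traj(x)
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- joint_kmeans(X, k, n_restarts = 100L)
  ref_labels <- reference$labels
  m <- max(2L, floor(frac * n))
  rand_scores <- numeric(n_resamples)
  ari_scores <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(n, m)
    sub <- joint_kmeans(X[idx, , drop = FALSE], k, n_restarts = n_restarts)
    rand_scores[r] <- rand_index(ref_labels[idx], sub$labels)
    ari_scores[r] <- adjusted_rand_index(ref_labels[idx], sub$labels)
  }
  structure(list(k = as.integer(k), rand_scores = rand_scores,
                 mean_rand = mean(rand_scores), ari_scores = ari_scores,
                 mean_ari = mean(ari_scores)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability of k = %d over %d resamples:\n", x$k,
              length(x$rand_scores)))
  cat(sprintf("  mean Rand %.3f (range %.3f-%.3f), mean ARI %.3f\n",
              x$mean_rand, min(x$rand_scores), max(x$rand_scores), x$mean_ari))
  invisible(x)
}
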