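# Nonparametric cluster-validity indices and partition-agreement measures.
#
# All three indices are computed on the flattened trajectory vectors.
# Calinski-Harabasz: higher is better; Ray-Turi and Davies-Bouldin: lower is
# better.

check_partition <- function(X, labels, k) {
  if (length(labels) != nrow(X)) stopf("labels do not match the data rows")
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) stopf("degenerate partition: empty cluster present")
  if (k < 2) stopf("indices require at least 2 clusters")
  sizes
}

index_parts <- function(X, labels, k) {
  sizes <- check_partition(X, labels, k)
  C <- rowsum(X, labels) / sizes
  grand <- colMeans(X)
  within <- sum((X - C[labels, , drop = FALSE])^2)
  between <- sum(sizes * rowSums(sweep(C, 2, grand)^2))
  list(C = C, sizes = sizes, within = within, between = between)
}

solution_labels <- function(solution) {
  if (inherits(solution, "cluster_solution")) solution$labels
  else as.integer(solution)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `(B / (k - 1)) / (W / (n - k))`, where `B` is the dispersion of cluster
#' centroids around the grand mean (weighted by cluster size) and `W` the
#' total within-cluster squared distance. Higher values indicate better
#' separated, more compact clusters.
#'
#' @param x A `trajectory_matrix` or numeric matrix.
#' @param solution A `cluster_solution` (or an integer label vector).
#' @return Scalar index value.
#' @export
calinski_harabasz <- function(x, solution) {
  X <- coerce_traj(x)
  labels <- solution_labels(solution)
  k <- max(labels)
  p <- index_parts(X, labels, k)
  n <- nrow(X)
  if (n == k) stopf("Calinski-Harabasz undefined for k = n (zero within df)")
  (p$between / (k - 1)) / (p$within / (n - k))
}

#' Ray-Turi index
#'
#' Mean within-cluster squared distance divided by the minimum squared
#' distance between any two cluster centroids. Lower is better.
#'
#' @inheritParams calinski_harabasz
#' @return Scalar index value.
#' @export
ray_turi <- function(x, solution) {
  X <- coerce_traj(x)
  labels <- solution_labels(solution)
  k <- max(labels)
  p <- index_parts(X, labels, k)
  d2 <- dist2_to_centroids(p$C, p$C)
  min_sep <- min(d2[upper.tri(d2)])
  if (min_sep == 0) stopf("coincident centroids: Ray-Turi undefined")
  (p$within / nrow(X)) / min_sep
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity
#' `max_j (s_i + s_j) / d(c_i, c_j)`, where `s_i` is the mean (unsquared)
#' distance of cluster members to their centroid and `d` the centroid
#' distance. Lower is better.
#'
#' @inheritParams calinski_harabasz
#' @return Scalar index value.
#' @export
davies_bouldin <- function(x, solution) {
  X <- coerce_traj(x)
  labels <- solution_labels(solution)
  k <- max(labels)
  p <- index_parts(X, labels, k)
  memb_dist <- sqrt(rowSums((X - p$C[labels, , drop = FALSE])^2))
  s <- as.vector(tapply(memb_dist, factor(labels, seq_len(k)), mean))
  dC <- sqrt(dist2_to_centroids(p$C, p$C))
  R <- outer(s, s, "+") / dC
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

align_partitions <- function(labels_a, labels_b) {
  na <- names(labels_a); nb <- names(labels_b)
  if (!is.null(na) && !is.null(nb)) {
    if (!setequal(na, nb)) stopf("partitions are over different element sets")
    labels_b <- labels_b[na]
  } else if (length(labels_a) != length(labels_b)) {
    stopf("partitions have different lengths")
  }
  list(a = as.integer(factor(labels_a)), b = as.integer(factor(labels_b)))
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree: pairs placed in
#' the same cluster in both, or in different clusters in both. 1 means the
#' partitions are identical up to relabeling. If both label vectors are
#' named, elements are matched by name.
#'
#' @param labels_a,labels_b Cluster label vectors over the same elements.
#' @return Scalar in `[0, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  p <- align_partitions(labels_a, labels_b)
  n <- length(p$a)
  if (n < 2) stopf("need at least 2 elements")
  tab <- table(p$a, p$b)
  choose2 <- function(x) x * (x - 1) / 2
  total <- choose2(n)
  same_both <- sum(choose2(tab))
  same_a <- sum(choose2(rowSums(tab)))
  same_b <- sum(choose2(colSums(tab)))
  (total + 2 * same_both - same_a - same_b) / total
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance agreement under the permutation model;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @inheritParams rand_index
#' @return Scalar (can be slightly negative).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  p <- align_partitions(labels_a, labels_b)
  n <- length(p$a)
  if (n < 2) stopf("need at least 2 elements")
  tab <- table(p$a, p$b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_ind <- (sum_a + sum_b) / 2
  if (max_ind == expected) return(1)
  (sum_ij - expected) / (max_ind - expected)
}

#' Fit-index report for one cluster solution
#'
#' Computes the three validity indices and applies the small-cluster
#' exclusion rule: a solution is flagged excluded when any cluster holds
#' fewer members than `min_cluster_size` (a count when `>= 1`, otherwise a
#' fraction of the sample).
#'
#' @inheritParams calinski_harabasz
#' @param min_cluster_size Exclusion threshold (default 0.15 of the sample).
#' @return One-row data frame: `k`, `calinski_harabasz`, `ray_turi`,
#'   `davies_bouldin`, `min_size`, `excluded`, `reason`.
#' @export
fit_indices <- function(x, solution, min_cluster_size = 0.15) {
  X <- coerce_traj(x)
  labels <- solution_labels(solution)
  k <- max(labels)
  threshold <- if (min_cluster_size < 1) min_cluster_size * nrow(X) else min_cluster_size
  min_size <- min(tabulate(labels, k))
  excluded <- min_size < threshold
  data.frame(
    k = k,
    calinski_harabasz = calinski_harabasz(X, labels),
    ray_turi = ray_turi(X, labels),
    davies_bouldin = davies_bouldin(X, labels),
    min_size = min_size,
    excluded = excluded,
    reason = if (excluded)
      sprintf("cluster with %d members below threshold %.1f", min_size, threshold)
    else "")
}
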