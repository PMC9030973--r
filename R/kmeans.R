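# Joint-trajectory k-means.
#
# Users are clustered on their joint (therapy, social) weekly trajectories,
# flattened to a single 44-entry vector per user, under plain Euclidean
# distance: both dimensions share the same ordinal 1-4 scale, so they are
# commensurate and no per-dimension normalization is applied. The algorithm
# is Lloyd's alternating assignment/update ("hill-climbing EM") with many
# restarts cycling through three initialization schemes, mirroring how
# trajectory k-means implementations alternate their starting conditions.

coerce_traj <- function(x) {
  m <- if (inherits(x, "trajectory_matrix")) as.matrix(x) else as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}

#' Euclidean distance between two joint trajectories
#'
#' Distance between two 2 x n-week trajectories (or any two equally shaped
#' numeric arrays), computed over the flattened entries. Both trajectory
#' dimensions are weighted equally since they share the same 1-4 level
#' scale.
#'
#' @param a,b Numeric vectors/matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
joint_distance <- function(a, b) {
  if (length(a) != length(b) || !identical(dim(a), dim(b)))
    stopf("trajectories must have identical shape")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

# Squared Euclidean distances, n x k, via the expanded-square identity.
dist2_to_centroids <- function(X, C) {
  D <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

init_centroids <- function(X, k, scheme) {
  n <- nrow(X)
  if (scheme == "random_partition") {
    labels <- sample(rep_len(seq_len(k), n))
    rowsum(X, labels) / as.vector(table(labels))
  } else if (scheme == "random_seeds") {
    X[sample.int(n, k), , drop = FALSE]
  } else {  # farthest-first (greedy max-min) from a random start
    seeds <- integer(k)
    seeds[1] <- sample.int(n, 1)
    mind2 <- dist2_to_centroids(X, X[seeds[1], , drop = FALSE])[, 1]
    for (j in seq_len(k - 1)) {
      seeds[j + 1] <- which.max(mind2)
      d2 <- dist2_to_centroids(X, X[seeds[j + 1], , drop = FALSE])[, 1]
      mind2 <- pmin(mind2, d2)
    }
    X[seeds, , drop = FALSE]
  }
}

lloyd_once <- function(X, k, scheme, max_iter) {
  n <- nrow(X)
  C <- init_centroids(X, k, scheme)
  labels <- rep(0L, n)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- dist2_to_centroids(X, C)
    new_labels <- max.col(-D, ties.method = "first")
    # empty-cluster repair: reseed with the point farthest from its centroid
    repeat {
      empties <- which(tabulate(new_labels, k) == 0)
      if (length(empties) == 0) break
      j <- empties[1]
      far <- which.max(D[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
      D[far, ] <- Inf; D[far, j] <- 0
    }
    trace <- c(trace, sum(D[cbind(seq_len(n), new_labels)]))
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    C <- rowsum(X, labels) / tabulate(labels, k)
  }
  inertia <- sum(dist2_to_centroids(X, C)[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = C, inertia = inertia,
       converged = converged, trace = trace)
}

# Relabel clusters by order of first appearance so the labelling is
# deterministic given the partition.
canonicalize_labels <- function(labels, centroids) {
  first <- match(seq_len(nrow(centroids)), labels)
  ord <- order(first)
  map <- integer(nrow(centroids))
  map[ord] <- seq_len(nrow(centroids))
  list(labels = map[labels], centroids = centroids[ord, , drop = FALSE])
}

#' K-means clustering for joint 2D trajectories
#'
#' Partitions users into `k` clusters by Lloyd's algorithm on the flattened
#' joint trajectories, repeated over `n_restarts` random initializations and
#' keeping the restart with the lowest total within-cluster squared distance
#' (inertia). Restarts cycle through three initialization schemes: random
#' partition, k distinct random users as seeds, and greedy farthest-first
#' seeding. Clusters emptied during iteration are reseeded with the point
#' currently farthest from its assigned centroid, so `k` is preserved.
#'
#' @param x A `trajectory_matrix` or numeric matrix (users x features).
#' @param k Number of clusters, `2 <= k <= n`.
#' @param n_restarts Number of restarts (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return Object of class `cluster_solution`: `k`, `labels` (named integer
#'   vector), `centroids` (k x features), `inertia`, `n_per_cluster`,
#'   `converged`, `best_of`, and the inertia `trace` of the winning restart
#'   (one value per iteration, non-increasing).
#' @export
joint_kmeans <- function(x, k, n_restarts = 100L, seed = NULL,
                         max_iter = 100L) {
  X <- coerce_traj(x)
  n <- nrow(X)
  if (n == 0) stopf("empty input")
  if (k < 2 || k > n) stopf("k must satisfy 2 <= k <= n_users (k=%d, n=%d)", k, n)
  if (!is.null(seed)) set.seed(seed)
  schemes <- c("random_partition", "random_seeds", "farthest_first")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(X, k, schemes[(r - 1L) %% 3L + 1L], max_iter)
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  cl <- canonicalize_labels(best$labels, best$centroids)
  labels <- stats::setNames(cl$labels, rownames(X))
  structure(
    list(k = as.integer(k), labels = labels, centroids = cl$centroids,
         inertia = best$inertia,
         n_per_cluster = tabulate(cl$labels, k),
         converged = best$converged, best_of = as.integer(n_restarts),
         trace = best$trace),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Joint-trajectory k-means solution: k = %d (best of %d restarts)\n",
              x$k, x$best_of))
  cat(sprintf("  cluster sizes: %s\n", paste(x$n_per_cluster, collapse = ", ")))
  cat(sprintf("  inertia: %.3f | converged: %s\n", x$inertia, x$converged))
  invisible(x)
}

#' Cluster centroids as weekly trajectories
#'
#' Reshapes the flattened centroids of a [joint_kmeans()] solution into a
#' long data frame of mean weekly activity levels per cluster and dimension,
#' convenient for plotting profile trajectories.
#'
#' @param solution A `cluster_solution` fitted on a trajectory matrix
#'   (features ordered therapy weeks then social weeks).
#' @return Data frame with `cluster`, `dimension`, `week`, `level`.
#' @export
centroid_trajectories <- function(solution) {
  C <- solution$centroids
  n_weeks <- ncol(C) / 2
  do.call(rbind, lapply(seq_len(nrow(C)), function(j) {
    data.frame(cluster = j,
               dimension = rep(c("therapy", "social"), each = n_weeks),
               week = rep(seq_len(n_weeks), 2),
               level = c(C[j, seq_len(n_weeks)],
                         C[j, n_weeks + seq_len(n_weeks)]))
  }))
}
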