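## Clustering algorithms over protein profiles: agglomerative hierarchical
## methods, Lloyd K-means, neural gas, and fuzzy C-means.

new_clustering <- function(labels, k, algorithm, distance = "euclidean",
                           linkage = NULL, seed = NA_integer_, centers = NULL,
                           membership = NULL, details = list()) {
  stopifnot(all(labels >= 1), all(labels <= k))
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 algorithm = algorithm, distance = distance,
                 linkage = linkage, seed = seed, centers = centers,
                 membership = membership, details = details),
            class = "protein_clustering")
}

#' @export
print.protein_clustering <- function(x, ...) {
  desc <- x$algorithm
  if (!is.null(x$linkage)) desc <- paste0(desc, "/", x$linkage)
  cat(sprintf("Clustering: %s (%s distance), k = %d, n = %d\n",
              desc, x$distance, x$k, length(x$labels)))
  print(base::table(x$labels))
  invisible(x)
}

#' Agglomerative hierarchical cluster analysis
#'
#' Builds the merge tree with [stats::hclust()]. Single and complete linkage
#' realize the two opposing clustering properties (connectedness vs
#' compactness), average linkage is the compromise, and Ward's method merges
#' the pair of clusters whose union increases the within-cluster variance
#' least. Ward requires Euclidean distances (`ward.D2` criterion: the
#' Lance-Williams recurrence on squared distances, heights square-rooted).
#'
#' @param dm A `protein_dist` from [profile_dist()].
#' @param linkage One of `"single"`, `"complete"`, `"average"`, `"ward"`.
#' @return A `merge_tree` wrapping the `hclust` object plus linkage and
#'   metric tags.
#' @export
hca <- function(dm, linkage = c("average", "single", "complete", "ward")) {
  stopifnot(inherits(dm, "protein_dist"))
  linkage <- match.arg(linkage)
  if (nrow(dm$d) < 2) stop("need at least 2 profiles", call. = FALSE)
  if (anyNA(dm$d)) {
    stop("distance matrix contains NA (degenerate correlation profiles)",
         call. = FALSE)
  }
  if (linkage == "ward" && dm$metric != "euclidean") {
    stop("Ward linkage requires Euclidean distances", call. = FALSE)
  }
  method <- c(single = "single", complete = "complete", average = "average",
              ward = "ward.D2")[[linkage]]
  h <- hclust(as.dist(dm$d), method = method)
  structure(list(hclust = h, linkage = linkage, metric = dm$metric,
                 n = nrow(dm$d), ids = dm$ids),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("Hierarchical merge tree: %d leaves, %s linkage (%s distance)\n",
              x$n, x$linkage, x$metric))
  invisible(x)
}

#' Cut a merge tree into k clusters
#'
#' The partition after `n - k` merges — a horizontal cut through the tree.
#' Labels are renumbered by first appearance.
#'
#' @param tree A `merge_tree` from [hca()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `protein_clustering`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "merge_tree"))
  if (!is_count(k, 1) || k > tree$n) {
    stop(sprintf("k must be an integer in [1, %d]", tree$n), call. = FALSE)
  }
  labels <- relabel_first_appearance(cutree(tree$hclust, k = k))
  new_clustering(labels, k, "hca", distance = tree$metric,
                 linkage = tree$linkage)
}

#' Merge-distance curve of a hierarchical tree
#'
#' For each possible cluster number `k`, the distance (merge height) at
#' which the two clusters were merged to produce that `k`-clustering. A
#' "knee" in this curve — a jump in merge heights — indicates a natural
#' cluster number; it is estimated as the `k` maximizing the second
#' difference of heights over `k`.
#'
#' @param tree A `merge_tree`.
#' @return A data frame (`k`, `height`) ordered from `k = n - 1` down to 1,
#'   with a `knee` attribute (NA when the tree is too small).
#' @export
merge_distance_curve <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  h <- tree$hclust$height # ascending merge order; merge i yields n - i clusters
  n <- tree$n
  out <- data.frame(k = n - seq_along(h), height = h)
  out <- out[order(-out$k), , drop = FALSE]
  rownames(out) <- NULL
  knee <- NA_integer_
  if (n >= 4) {
    hk <- function(k) h[n - k]
    ks <- 2:(n - 2)
    d2 <- vapply(ks, function(k) hk(k - 1) - 2 * hk(k) + hk(k + 1), 0)
    knee <- ks[which.max(d2)]
  }
  attr(out, "knee") <- knee
  out
}

#' K-means clustering (Lloyd's algorithm)
#'
#' Initial cluster centers are sampled at random from the input profiles;
#' Lloyd iterations assign each profile to its nearest center (Euclidean)
#' and recompute centers as cluster means until the assignment reaches a
#' fixpoint or `max_iter`. The within-cluster sum of squares is asserted
#' non-increasing at every iteration. A cluster that empties is re-seeded
#' with the profile farthest from its current center (count recorded in
#' `details$reseeds`). Deterministic given `seed`.
#'
#' @param X Numeric matrix or `profile_matrix` (rows = proteins).
#' @param k Number of clusters, `k <= nrow(X)`.
#' @param seed Integer seed.
#' @param max_iter Iteration cap (default 100).
#' @return A `protein_clustering` with `centers` and
#'   `details$within_ss`, `details$iterations`, `details$reseeds`.
#' @export
kmeans_cluster <- function(X, k, seed = 1, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("missing cells are not tolerated; impute first",
                     call. = FALSE)
  if (!is_count(k, 1) || k > n) stop("k must be in [1, n]", call. = FALSE)
  set.seed(seed)
  centers <- X[sample(n, k), , drop = FALSE]
  assign_prev <- rep(0L, n)
  obj_prev <- Inf
  reseeds <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- rowdist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    ## re-seed empty clusters from the datum farthest from its center
    empty <- setdiff(seq_len(k), unique(assign))
    while (length(empty) > 0) {
      far <- which.max(d2[cbind(seq_len(n), assign)])
      centers[empty[1], ] <- X[far, ]
      reseeds <- reseeds + 1L
      d2 <- rowdist2(X, centers)
      assign <- max.col(-d2, ties.method = "first")
      empty <- setdiff(seq_len(k), unique(assign))
    }
    obj <- sum(d2[cbind(seq_len(n), assign)])
    stopifnot(obj <= obj_prev + 1e-8 * max(1, obj_prev)) # Lloyd monotonicity
    obj_prev <- obj
    if (identical(assign, assign_prev) || iter >= max_iter) break
    assign_prev <- assign
    centers <- centroids(X, assign, k)
  }
  centers <- centroids(X, assign, k)
  obj <- sum(rowdist2(X, centers)[cbind(seq_len(n), assign)])
  new_clustering(assign, k, "kmeans", seed = seed, centers = centers,
                 details = list(within_ss = obj, iterations = iter,
                                reseeds = reseeds))
}

#' Neural gas clustering
#'
#' Online vector quantization that softens K-means' dependence on the
#' initial centers: every presented profile updates *all* centers, weighted
#' by their distance rank ("neighborhood ranking"). The center of rank `r`
#' (0 = nearest) moves toward the datum by `eps(t) * exp(-r / lambda(t))`;
#' both the step size `eps` and the neighborhood range `lambda` decay
#' exponentially from their start to end values over `epochs * n`
#' presentations. Final hard labels assign each profile to its nearest
#' center. Initial centers are sampled from the data; deterministic given
#' `seed`.
#'
#' @inheritParams kmeans_cluster
#' @param epochs Passes over the data (default 50).
#' @param eps Step-size schedule `c(start, end)` (default `c(0.5, 0.005)`).
#' @param lambda Neighborhood-range schedule `c(start, end)`; default start
#'   is `k / 2`, end 0.01.
#' @return A `protein_clustering` with `centers`.
#' @export
neural_gas <- function(X, k, seed = 1, epochs = 50, eps = c(0.5, 0.005),
                       lambda = c(k / 2, 0.01)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("missing cells are not tolerated; impute first",
                     call. = FALSE)
  if (!is_count(k, 1) || k > n) stop("k must be in [1, n]", call. = FALSE)
  set.seed(seed)
  centers <- X[sample(n, k), , drop = FALSE]
  t_max <- epochs * n
  t <- 0
  for (e in seq_len(epochs)) {
    ord <- sample(n)
    for (i in ord) {
      t <- t + 1
      frac <- t / t_max
      eps_t <- eps[1] * (eps[2] / eps[1])^frac
      lam_t <- lambda[1] * (lambda[2] / lambda[1])^frac
      diff <- sweep(centers, 2, X[i, ], "-")
      r <- rank(rowSums(diff^2), ties.method = "first") - 1
      centers <- centers - (eps_t * exp(-r / lam_t)) * diff
    }
  }
  d2 <- rowdist2(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  new_clustering(labels, k, "neuralgas", seed = seed, centers = centers,
                 details = list(epochs = epochs, eps = eps, lambda = lambda))
}

#' Fuzzy C-means clustering
#'
#' Each protein receives a membership in `[0, 1]` to every cluster (rows of
#' the membership matrix sum to 1), alternating membership and
#' weighted-mean center updates (via [e1071::cmeans()], fuzzifier `m`)
#' until convergence. For comparison with hard clusterings each protein is
#' assigned to the cluster with maximal membership (ties resolved toward
#' the lowest cluster index). Initial centers are sampled from the data;
#' deterministic given `seed`.
#'
#' @inheritParams kmeans_cluster
#' @param m Fuzzifier > 1 (default 2); `m -> 1` approaches hard assignment.
#' @param max_iter Iteration cap (default 200).
#' @return A `protein_clustering` with `centers` and an `n x k`
#'   `membership` matrix.
#' @export
fuzzy_cmeans <- function(X, k, m = 2, seed = 1, max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("missing cells are not tolerated; impute first",
                     call. = FALSE)
  if (!is_count(k, 1) || k > n) stop("k must be in [1, n]", call. = FALSE)
  if (!is.numeric(m) || m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  set.seed(seed)
  init <- X[sample(n, k), , drop = FALSE]
  ## coincident sampled centers would make memberships degenerate
  if (k > 1) init <- init + matrix(rnorm(k * ncol(X), 0, 1e-9), k)
  fit <- e1071::cmeans(X, centers = init, iter.max = max_iter, m = m,
                       method = "cmeans")
  u <- fit$membership
  labels <- max.col(u, ties.method = "first")
  new_clustering(labels, k, "fcm", seed = seed, centers = fit$centers,
                 membership = u,
                 details = list(m = m, iterations = fit$iter))
}

#' Cluster protein profiles with a named algorithm
#'
#' Unified front end used by the sweeps, reproducibility protocols and the
#' pipeline. Hierarchical algorithms build the distance matrix, the merge
#' tree and cut it at `k`; partitioning and fuzzy algorithms run seeded.
#'
#' @param X A `profile_matrix` or numeric matrix.
#' @param algorithm One of `"single"`, `"complete"`, `"average"`, `"ward"`
#'   (hierarchical, cut at `k`), `"kmeans"`, `"neuralgas"`, `"fcm"`.
#' @param k Number of clusters.
#' @param distance Distance for hierarchical algorithms: `"euclidean"`,
#'   `"pearson"`, `"upearson"`.
#' @param seed Integer seed (ignored by the deterministic hierarchical
#'   methods).
#' @param ... Passed to the underlying algorithm.
#' @return A `protein_clustering`.
#' @export
#' @examples
#' sim <- simulate_profile_matrix(c(8, 8), n_conditions = 3, sd = 0.05,
#'                                seed = 2)
#' cluster_profiles(sim$matrix, "ward", k = 2)
cluster_profiles <- function(X, algorithm, k, distance = "euclidean",
                             seed = 1, ...) {
  algorithm <- match.arg(algorithm, c("single", "complete", "average",
                                      "ward", "kmeans", "neuralgas", "fcm"))
  if (algorithm %in% c("single", "complete", "average", "ward")) {
    dm <- if (inherits(X, "protein_dist")) X else profile_dist(X, distance)
    cut_tree(hca(dm, linkage = algorithm), k)
  } else {
    Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
    switch(algorithm,
      kmeans = kmeans_cluster(Xm, k, seed = seed, ...),
      neuralgas = neural_gas(Xm, k, seed = seed, ...),
      fcm = fuzzy_cmeans(Xm, k, seed = seed, ...)
    )
  }
}

## TRUE for algorithms whose result depends on the seed
is_stochastic_algorithm <- function(algorithm) {
  algorithm %in% c("kmeans", "neuralgas", "fcm")
}
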