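## Cluster-result evaluation: Rand / adjusted Rand partition comparison,
## reproducibility protocols, Figure of Merit, and validity indexes.

check_partitions <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need at least 2 items", call. = FALSE)
}

## pair-counting summary of two partitions via the contingency table
pair_counts <- function(a, b) {
  tab <- base::table(a, b)
  n <- length(a)
  S <- sum(choose(tab, 2))          # pairs together in both
  Sa <- sum(choose(rowSums(tab), 2))
  Sb <- sum(choose(colSums(tab), 2))
  list(n = n, total = choose(n, 2), S = S, Sa = Sa, Sb = Sb)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which the two partitions agree — pairs placed
#' together in both, or apart in both. 1 means identical partitions, 0 no
#' agreement at all.
#'
#' @param a,b Cluster label vectors of equal length (any label coding;
#'   invariant under relabeling).
#' @return Value in `[0, 1]`.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 1/3
rand_index <- function(a, b) {
  check_partitions(a, b)
  pc <- pair_counts(a, b)
  (pc$S + (pc$total - pc$Sa - pc$Sb + pc$S)) / pc$total
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair agreement: observed together-pairs minus their
#' expectation under random partitions with the same margins, over the
#' maximum minus the expectation. 1.0 means the results are identical;
#' values near 0.0 indicate no similarity beyond chance. When the
#' correction denominator degenerates to zero (both partitions all
#' singletons, or both a single cluster) the value is 1 if the partitions
#' are identical and 0 otherwise.
#'
#' @inheritParams rand_index
#' @return Value `<= 1`.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same partition
adjusted_rand_index <- function(a, b) {
  check_partitions(a, b)
  pc <- pair_counts(a, b)
  expected <- pc$Sa * pc$Sb / pc$total
  denom <- (pc$Sa + pc$Sb) / 2 - expected
  if (denom == 0) {
    agree <- pc$S + (pc$total - pc$Sa - pc$Sb + pc$S)
    return(if (agree == pc$total) 1 else 0)
  }
  (pc$S - expected) / denom
}

#' Reproducibility protocol for seed-sensitive clustering algorithms
#'
#' Runs a stochastic algorithm `reps` times at fixed `k`, each repetition
#' re-sampling its initial cluster centers from the input (seeds derived
#' deterministically from the master seed), and computes the pairwise Rand
#' (default) or adjusted Rand similarity between every two runs. Low
#' off-diagonal values reveal an algorithm whose outcome depends strongly
#' on its initialization.
#'
#' @param X A `profile_matrix` or numeric matrix.
#' @param algorithm `"kmeans"`, `"neuralgas"` or `"fcm"`; deterministic
#'   algorithms are rejected (the protocol would be meaningless).
#' @param k Cluster number (default 20).
#' @param reps Repetitions (default 25).
#' @param seed Master seed.
#' @param measure `"rand"` (default) or `"ari"`.
#' @param ... Passed to the algorithm.
#' @return A `rand_matrix`: symmetric `reps x reps` similarity matrix with
#'   unit diagonal, plus method descriptor, per-run seeds and measure tag.
#' @export
reproducibility_protocol <- function(X, algorithm, k = 20, reps = 25,
                                     seed = 1, measure = c("rand", "ari"),
                                     ...) {
  measure <- match.arg(measure)
  if (!is_stochastic_algorithm(algorithm)) {
    stop("reproducibility protocol requires a seed-sensitive algorithm",
         call. = FALSE)
  }
  if (!is_count(reps, 2)) config_error("reps must be an integer >= 2")
  seeds <- vapply(seq_len(reps),
                  function(i) derive_seed(seed, paste0(algorithm, ":", i)),
                  integer(1))
  runs <- lapply(seeds, function(s) {
    cluster_profiles(X, algorithm, k, seed = s, ...)$labels
  })
  f <- if (measure == "rand") rand_index else adjusted_rand_index
  m <- diag(1, reps)
  for (i in seq_len(reps - 1)) {
    for (j in (i + 1):reps) {
      m[i, j] <- m[j, i] <- f(runs[[i]], runs[[j]])
    }
  }
  structure(list(similarity = m, algorithm = algorithm, k = k, reps = reps,
                 seeds = seeds, measure = measure),
            class = "rand_matrix")
}

#' @export
print.rand_matrix <- function(x, ...) {
  v <- x$similarity[upper.tri(x$similarity)]
  cat(sprintf(
    "%s similarity over %d %s runs (k = %d): mean %.3f, range [%.3f, %.3f]\n",
    if (x$measure == "rand") "Rand" else "Adjusted Rand",
    x$reps, x$algorithm, x$k, mean(v), min(v), max(v)))
  invisible(x)
}

#' Compare the reproducibility of two algorithms
#'
#' Two-sided Mann-Whitney rank-sum test on the two sets of off-diagonal
#' similarity values, with per-algorithm mean and SD. The pairwise values
#' within a matrix are not statistically independent (every run enters
#' `reps - 1` pairs), so the p-value is a descriptive pseudo-replication
#' summary rather than an exactly calibrated test.
#'
#' @param m1,m2 `rand_matrix` objects with equal `reps` and `measure`.
#' @return An `algorithm_comparison` list: per-method mean/SD, the rank-sum
#'   statistic and p-value, and `lower`, the algorithm with the smaller mean
#'   similarity (lower reproducibility).
#' @export
compare_reproducibility <- function(m1, m2) {
  stopifnot(inherits(m1, "rand_matrix"), inherits(m2, "rand_matrix"))
  if (m1$reps != m2$reps || m1$measure != m2$measure) {
    stop("matrices must have the same reps and measure", call. = FALSE)
  }
  v1 <- m1$similarity[upper.tri(m1$similarity)]
  v2 <- m2$similarity[upper.tri(m2$similarity)]
  wt <- suppressWarnings(wilcox.test(v1, v2, exact = FALSE))
  structure(list(
    algorithms = c(m1$algorithm, m2$algorithm),
    mean = c(mean(v1), mean(v2)), sd = c(sd(v1), sd(v2)),
    statistic = unname(wt$statistic), p.value = wt$p.value,
    lower = c(m1$algorithm, m2$algorithm)[which.min(c(mean(v1), mean(v2)))],
    measure = m1$measure
  ), class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  cat(sprintf("%s: mean %.3f (sd %.3f)  vs  %s: mean %.3f (sd %.3f)\n",
              x$algorithms[1], x$mean[1], x$sd[1],
              x$algorithms[2], x$mean[2], x$sd[2]))
  cat(sprintf("rank-sum p = %.3g; lower reproducibility: %s\n",
              x$p.value, x$lower))
  invisible(x)
}

## ---- validity indexes ------------------------------------------------

#' Figure of Merit (leave-one-condition-out predictive power)
#'
#' For each left-out condition `e`, the data are clustered on the remaining
#' conditions and `FOM(e, k)` is the root mean squared deviation of each
#' protein's value in `e` from its cluster's mean in `e`; the aggregate
#' `FOM(k)` sums over all conditions. The adjusted form divides by
#' `sqrt((n - k) / n)` so curves remain comparable across `k`; lower is
#' better.
#'
#' @param X A `profile_matrix` or numeric matrix with >= 2 conditions.
#' @param algorithm Clustering algorithm name (see [cluster_profiles()]).
#' @param k_range Integer vector of cluster numbers.
#' @param seed Master seed (per-`k`, per-condition seeds are derived).
#' @param distance Distance for hierarchical algorithms.
#' @param ... Passed to the algorithm.
#' @return An `index_curve` data frame (`k`, `value` = adjusted FOM,
#'   `raw`), optimum rule minimize.
#' @export
figure_of_merit <- function(X, algorithm, k_range, seed = 1,
                            distance = "euclidean", ...) {
  Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  p <- ncol(Xm)
  if (p < 2) stop("need at least 2 conditions", call. = FALSE)
  vals <- raw <- rep(NA_real_, length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k >= n) next
    tot <- 0
    for (e in seq_len(p)) {
      cl <- cluster_profiles(Xm[, -e, drop = FALSE], algorithm, k,
                             distance = distance,
                             seed = derive_seed(seed, paste0("fom:", k, ":", e)),
                             ...)
      fitted <- ave(Xm[, e], cl$labels)
      tot <- tot + sqrt(mean((Xm[, e] - fitted)^2))
    }
    raw[ki] <- tot
    vals[ki] <- tot / sqrt((n - k) / n)
  }
  new_index_curve("fom", k_range, vals, "minimize", extra = list(raw = raw))
}

#' Calinski-Harabasz index
#'
#' Ratio of the between-cluster to the within-cluster sum of squared
#' Euclidean deviations, each scaled by its degrees of freedom:
#' `(B / (k - 1)) / (W / (n - k))`. Larger values indicate compact,
#' well-separated clusters; a degenerate partition with `W = 0` yields `NA`.
#'
#' @param X Numeric matrix or `profile_matrix`.
#' @param labels Integer cluster labels (no empty cluster; `2 <= k <= n-1`).
#' @return Index value or `NA`.
#' @export
calinski_harabasz <- function(X, labels) {
  Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  k <- length(unique(labels))
  if (k < 2 || k > n - 1) return(NA_real_)
  W <- within_ss(Xm, labels)
  B <- total_ss(Xm) - W
  if (W <= 0) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Index I
#'
#' `((1/k) * (E1 / Ek) * Dk)^p` where `Ek` is the summed Euclidean distance
#' of every profile to its cluster center, `E1` the same for a single
#' global cluster, and `Dk` the maximum distance between two cluster
#' centers. Larger is better; defined for `k >= 2` (`Dk` needs two
#' centers), `NA` when `Ek = 0`.
#'
#' @inheritParams calinski_harabasz
#' @param p Power exponent (default 2).
#' @return Index value or `NA`.
#' @export
index_I <- function(X, labels, p = 2) {
  Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  k <- length(unique(labels))
  if (k < 2 || k > n) return(NA_real_)
  labels <- relabel_first_appearance(labels)
  C <- centroids(Xm, labels, k)
  Ek <- sum(sqrt(rowSums((Xm - C[labels, , drop = FALSE])^2)))
  if (Ek <= 0) return(NA_real_)
  E1 <- sum(sqrt(rowSums(sweep(Xm, 2, colMeans(Xm))^2)))
  Dk <- max(dist(C))
  ((1 / k) * (E1 / Ek) * Dk)^p
}

#' Davies-Bouldin index (Halkidi variant)
#'
#' For each cluster, the worst-case ratio `(s_i + s_j) / d(c_i, c_j)` over
#' all other clusters, averaged over clusters, where `s_i` is the
#' root-mean-squared distance of cluster members to their centroid (the
#' intra-cluster error sum of squares, per member) and `d` the Euclidean
#' centroid distance. An optimal clustering is indicated by the *minimal*
#' value; coincident centroids yield `NA`.
#'
#' @inheritParams calinski_harabasz
#' @return Index value or `NA`.
#' @export
davies_bouldin <- function(X, labels) {
  Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
  k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  labels <- relabel_first_appearance(labels)
  C <- centroids(Xm, labels, k)
  s <- vapply(seq_len(k), function(j) {
    idx <- which(labels == j)
    sqrt(mean(rowSums(sweep(Xm[idx, , drop = FALSE], 2, C[j, ])^2)))
  }, 0)
  dC <- as.matrix(dist(C))
  if (any(dC[upper.tri(dC)] == 0)) return(NA_real_)
  mean(vapply(seq_len(k), function(i) {
    max(((s[i] + s[-i]) / dC[i, -i]))
  }, 0))
}

#' Krzanowski-Lai index from a within-SS sequence
#'
#' `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` and
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|`, with `W(k)` the within-cluster sum of
#' squares at cluster number `k` (same algorithm and data across the
#' sequence) and `p` the number of conditions. The cluster number maximizing
#' KL is the index's suggestion; `KL` is `NA` where `DIFF(k+1) = 0` or a
#' neighbor is unavailable.
#'
#' @param W Numeric vector of within-SS values at consecutive cluster
#'   numbers `k_values`.
#' @param k_values Strictly increasing consecutive integers (same length as
#'   `W`).
#' @param p Number of features (conditions).
#' @return An `index_curve` data frame (`k`, `value`), optimum rule
#'   maximize; ends of the sequence are `NA` (no neighbor).
#' @export
krzanowski_lai <- function(W, k_values, p) {
  stopifnot(length(W) == length(k_values), p >= 1)
  if (length(k_values) > 1 && any(diff(k_values) != 1)) {
    stop("k_values must be consecutive integers", call. = FALSE)
  }
  m <- length(W)
  DIFF <- rep(NA_real_, m) # DIFF[i] defined when k_values[i] >= 2 and i >= 2
  for (i in seq_len(m)) {
    if (i >= 2 && k_values[i] >= 2) {
      DIFF[i] <- (k_values[i] - 1)^(2 / p) * W[i - 1] -
        k_values[i]^(2 / p) * W[i]
    }
  }
  KL <- rep(NA_real_, m)
  for (i in seq_len(m - 1)) {
    if (!is.na(DIFF[i]) && !is.na(DIFF[i + 1]) && DIFF[i + 1] != 0) {
      KL[i] <- abs(DIFF[i]) / abs(DIFF[i + 1])
    }
  }
  new_index_curve("krzanowski_lai", k_values, KL, "maximize")
}

new_index_curve <- function(name, k, value, rule, extra = list()) {
  out <- data.frame(k = as.integer(k), value = value)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  ok <- which(!is.na(out$value) & is.finite(out$value))
  opt_k <- if (length(ok)) {
    out$k[ok][if (rule == "maximize") which.max(out$value[ok]) else
      which.min(out$value[ok])]
  } else {
    NA_integer_
  }
  structure(out, index = name, rule = rule, opt_k = opt_k,
            class = c("index_curve", "data.frame"))
}

#' @export
print.index_curve <- function(x, ...) {
  cat(sprintf("Validity index '%s' (%s): optimum at k = %s\n",
              attr(x, "index"), attr(x, "rule"),
              ifelse(is.na(attr(x, "opt_k")), "NA", attr(x, "opt_k"))))
  print(as.data.frame(x))
  invisible(x)
}

#' Sweep cluster numbers and evaluate validity indexes
#'
#' Clusters the profiles once per `k` (seeded deterministically per method
#' and `k`) and evaluates the requested indexes on each partition. The
#' Krzanowski-Lai index consumes the within-SS sequence across the sweep
#' (using the closed-form `W(1)` = total SS below `k_min`); per-`k` failures
#' are recorded as `NA` and the sweep continues.
#'
#' @param X A `profile_matrix` or numeric matrix.
#' @param algorithm Clustering algorithm name.
#' @param k_range Integer vector of cluster numbers within `[2, n - 1]`.
#' @param indexes Any of `"calinski_harabasz"`, `"index_i"`,
#'   `"davies_bouldin"`, `"krzanowski_lai"`, `"fom"`.
#' @param seed Master seed.
#' @param distance Distance for hierarchical algorithms.
#' @param ... Passed to the algorithm.
#' @return Named list of `index_curve` objects (each with an `opt_k`
#'   attribute marking the argmax/argmin).
#' @export
index_sweep <- function(X, algorithm, k_range,
                        indexes = c("calinski_harabasz", "index_i",
                                    "davies_bouldin", "krzanowski_lai"),
                        seed = 1, distance = "euclidean", ...) {
  indexes <- match.arg(indexes, c("calinski_harabasz", "index_i",
                                  "davies_bouldin", "krzanowski_lai", "fom"),
                       several.ok = TRUE)
  Xm <- if (inherits(X, "profile_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop(sprintf("k_range must lie within [2, %d]", n - 1), call. = FALSE)
  }
  labels_at <- function(k) {
    tryCatch(
      cluster_profiles(Xm, algorithm, k, distance = distance,
                       seed = derive_seed(seed, paste0(algorithm, ":", k)),
                       ...)$labels,
      error = function(e) NULL
    )
  }
  labs <- lapply(k_range, labels_at)
  out <- list()
  if ("calinski_harabasz" %in% indexes) {
    v <- vapply(labs, function(l) if (is.null(l)) NA_real_ else
      calinski_harabasz(Xm, l), 0)
    out$calinski_harabasz <- new_index_curve("calinski_harabasz", k_range, v,
                                             "maximize")
  }
  if ("index_i" %in% indexes) {
    v <- vapply(labs, function(l) if (is.null(l)) NA_real_ else
      index_I(Xm, l), 0)
    out$index_i <- new_index_curve("index_i", k_range, v, "maximize")
  }
  if ("davies_bouldin" %in% indexes) {
    v <- vapply(labs, function(l) if (is.null(l)) NA_real_ else
      davies_bouldin(Xm, l), 0)
    out$davies_bouldin <- new_index_curve("davies_bouldin", k_range, v,
                                          "minimize")
  }
  if ("krzanowski_lai" %in% indexes) {
    ## W sequence over contiguous k: prepend k = 1 (closed form) when the
    ## sweep starts at 2 so KL is defined at k_min
    ks <- k_range
    Wlabs <- labs
    if (ks[1] == 2) {
      ks <- c(1L, ks)
      Wlabs <- c(list(rep(1L, n)), Wlabs)
    }
    contiguous <- length(ks) < 2 || all(diff(ks) == 1)
    if (contiguous) {
      W <- vapply(Wlabs, function(l) if (is.null(l)) NA_real_ else
        within_ss(Xm, l), 0)
      kl <- krzanowski_lai(W, ks, ncol(Xm))
      keep <- kl$k %in% k_range
      out$krzanowski_lai <- new_index_curve("krzanowski_lai", kl$k[keep],
                                            kl$value[keep], "maximize")
    } else {
      out$krzanowski_lai <- new_index_curve("krzanowski_lai", k_range,
                                            rep(NA_real_, length(k_range)),
                                            "maximize")
    }
  }
  if ("fom" %in% indexes) {
    out$fom <- figure_of_merit(X, algorithm, k_range, seed = seed,
                               distance = distance, ...)
  }
  out
}

#' Mean adjusted-Rand similarity matrix across algorithms
#'
#' For every pair of method descriptors and every cluster number in
#' `k_range`, computes the adjusted Rand (or plain Rand) index between the
#' two partitions, and reports the mean over `k` — a compact picture of
#' which algorithm families produce congruent clusterings on a dataset.
#'
#' @param X A `profile_matrix` or numeric matrix.
#' @param methods Named list of descriptors, each a list with `algorithm`
#'   and optionally `distance` (default `"euclidean"`).
#' @param k_range Integer vector of cluster numbers.
#' @param seed Master seed (per-method, per-`k` seeds are derived).
#' @param measure `"ari"` (default) or `"rand"`.
#' @return Symmetric matrix of mean similarity values with unit diagonal,
#'   rows/columns named by the method descriptors.
#' @export
algorithm_similarity_matrix <- function(X, methods, k_range, seed = 1,
                                        measure = c("ari", "rand")) {
  measure <- match.arg(measure)
  if (length(methods) < 2) stop("need at least 2 methods", call. = FALSE)
  if (is.null(names(methods))) {
    names(methods) <- vapply(methods, function(m) {
      paste(c(m$algorithm, m$distance), collapse = "/")
    }, "")
  }
  f <- if (measure == "ari") adjusted_rand_index else rand_index
  labs <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    dst <- if (is.null(m$distance)) "euclidean" else m$distance
    lapply(k_range, function(k) {
      tryCatch(
        cluster_profiles(X, m$algorithm, k, distance = dst,
                         seed = derive_seed(seed, paste0(nm, ":", k)))$labels,
        error = function(e) NULL
      )
    })
  })
  nm <- length(methods)
  out <- diag(1, nm)
  dimnames(out) <- list(names(methods), names(methods))
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      vals <- mapply(function(a, b) {
        if (is.null(a) || is.null(b)) NA_real_ else f(a, b)
      }, labs[[i]], labs[[j]])
      out[i, j] <- out[j, i] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}
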