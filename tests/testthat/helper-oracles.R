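## Independent oracles used across the test files. All are deliberately
## naive (enumeration / O(n^3) re-scans) and share no code with the package.

## Naive agglomerative clustering: recompute every inter-cluster distance
## from the raw pairwise matrix at every step (no Lance-Williams updates).
## For ward, X is required and the merge cost is the within-SS increase,
## reported on the ward.D2 height scale sqrt(2 * delta_SS).
naive_hca <- function(d, linkage, X = NULL) {
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1) # partition after each merge
  cluster_dist <- function(a, b) {
    cross <- d[a, b, drop = FALSE]
    switch(linkage,
      single = min(cross),
      complete = max(cross),
      average = mean(cross),
      ward = {
        ca <- colMeans(X[a, , drop = FALSE])
        cb <- colMeans(X[b, , drop = FALSE])
        dss <- (length(a) * length(b) / (length(a) + length(b))) *
          sum((ca - cb)^2)
        sqrt(2 * dss)
      }
    )
  }
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    m <- length(members)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dd <- cluster_dist(members[[i]], members[[j]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights[step] <- best_d
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members <- members[-best[2]]
    lab <- integer(n)
    for (ci in seq_along(members)) lab[members[[ci]]] <- ci
    partitions[[step]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

## pair-by-pair Rand / adjusted Rand, looping over all item pairs
oracle_rand <- function(a, b, adjusted = FALSE) {
  n <- length(a)
  s_both <- s_apart <- together_a <- together_b <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      ta <- a[i] == a[j]
      tb <- b[i] == b[j]
      if (ta && tb) s_both <- s_both + 1
      if (!ta && !tb) s_apart <- s_apart + 1
      if (ta) together_a <- together_a + 1
      if (tb) together_b <- together_b + 1
    }
  }
  if (!adjusted) return((s_both + s_apart) / total)
  expected <- together_a * together_b / total
  denom <- (together_a + together_b) / 2 - expected
  if (denom == 0) {
    return(if (s_both + s_apart == total) 1 else 0)
  }
  (s_both - expected) / denom
}

## all set partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    pos <- length(labels) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max)) {
      recurse(c(labels, v), max(next_max, v + 1))
    }
  }
  recurse(integer(0), 1)
  out
}

## brute-force optimal k-partition of rows of X by within-cluster SS
brute_force_kmeans <- function(X, k) {
  n <- nrow(X)
  best <- NULL
  best_ss <- Inf
  for (labels in all_partitions(n)) {
    if (length(unique(labels)) != k) next
    ss <- 0
    for (g in unique(labels)) {
      idx <- which(labels == g)
      ctr <- colMeans(X[idx, , drop = FALSE])
      ss <- ss + sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
    }
    if (ss < best_ss) {
      best_ss <- ss
      best <- labels
    }
  }
  list(labels = best, within_ss = best_ss)
}

## three Gaussian blobs at 10-sigma separation in 5 conditions, 20 per blob
blob_fixture <- function(seed = 101, sd = 1, n_per = 20) {
  centers <- matrix(0, 3, 5)
  centers[1, 1] <- centers[2, 2] <- centers[3, 3] <- 10 * sd / sqrt(2)
  simulate_profile_matrix(rep(n_per, 3), centers = centers, sd = sd,
                          seed = seed)
}

## overlapping blobs (forced k far above the true structure) for
## reproducibility stress tests
overlap_fixture <- function(seed = 8) {
  set.seed(seed + 1)
  centers <- matrix(rnorm(10 * 5), 10, 5)
  simulate_profile_matrix(rep(15, 10), centers = centers, sd = 0.6,
                          seed = seed)
}

## random peptide table fixture for IO round trips
random_peptide_df <- function(n, seed) {
  set.seed(seed)
  data.frame(
    protein = sample(sprintf("P%02d", 1:5), n, replace = TRUE),
    peptide = sprintf("pep%03d", seq_len(n)),
    condition = sample(c("t0", "t1", "t2"), n, replace = TRUE),
    replicate = sample(c("r1", "r2"), n, replace = TRUE),
    ratio = round(runif(n, 0.1, 5), 4),
    stringsAsFactors = FALSE
  )
}
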