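test_that("Rand and adjusted Rand match hand-computed pair counts", {
  a <- c(1, 1, 2, 2)
  b <- c(1, 2, 1, 2)
  # agreements: 0 pairs together-together, 2 pairs apart-apart out of 6
  expect_equal(rand_index(a, b), 1 / 3)
  expect_equal(adjusted_rand_index(a, b), -0.5)
  expect_equal(rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, a), 1)
  # label-permutation invariance
  expect_equal(adjusted_rand_index(a, c(9, 9, 4, 4)), 1)
  expect_equal(rand_index(c(1, 1, 1, 2), c(2, 2, 2, 7)), 1)
  expect_error(rand_index(1:3, 1:4), "length")
})

test_that("degenerate partitions use the documented convention", {
  one <- rep(1, 5)
  expect_equal(adjusted_rand_index(one, one), 1)
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
  # all-singletons vs all-together: expected index equals the index
  expect_equal(adjusted_rand_index(1:5, one), 0)
  expect_equal(rand_index(1:5, one), 0)
})

test_that("indexes match the exhaustive pair-counting oracle on all small partitions", {
  for (n in 3:5) {
    parts <- all_partitions(n)
    for (i in seq_along(parts)) {
      for (j in seq_along(parts)) {
        a <- parts[[i]]; b <- parts[[j]]
        expect_equal(rand_index(a, b), oracle_rand(a, b, adjusted = FALSE))
        expect_equal(adjusted_rand_index(a, b), oracle_rand(a, b, adjusted = TRUE))
      }
    }
  }
  # sampled pairs for n = 6 keep runtime bounded
  parts6 <- all_partitions(6)
  set.seed(111)
  for (rep in 1:60) {
    a <- parts6[[sample(length(parts6), 1)]]
    b <- parts6[[sample(length(parts6), 1)]]
    expect_equal(adjusted_rand_index(a, b), oracle_rand(a, b, adjusted = TRUE))
  }
})

test_that("adjusted Rand agrees with the independent mclust implementation", {
  set.seed(113)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    a <- sample(sample(2:6, 1), n, replace = TRUE)
    b <- sample(sample(2:6, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("adjusted Rand is centered near zero for random partitions", {
  set.seed(127)
  ari <- replicate(200, adjusted_rand_index(sample(4, 60, replace = TRUE),
                                            sample(4, 60, replace = TRUE)))
  expect_lt(abs(mean(ari)), 0.01)
})

test_that("reproducibility protocol yields a valid, deterministic Rand matrix", {
  b <- blob_fixture(seed = 131)
  rm1 <- reproducibility_protocol(b$matrix, "kmeans", k = 3, reps = 6, seed = 5)
  rm2 <- reproducibility_protocol(b$matrix, "kmeans", k = 3, reps = 6, seed = 5)
  expect_identical(rm1$similarity, rm2$similarity)
  expect_equal(unname(diag(rm1$similarity)), rep(1, 6))
  expect_equal(rm1$similarity, t(rm1$similarity))
  expect_true(all(rm1$similarity >= 0 & rm1$similarity <= 1))
  # well-separated blobs reproduce almost perfectly for neural gas
  ng <- reproducibility_protocol(b$matrix, "neuralgas", k = 3, reps = 6,
                                 seed = 5)
  off <- ng$similarity[upper.tri(ng$similarity)]
  expect_true(all(off >= 0.99))
  expect_error(reproducibility_protocol(b$matrix, "ward", k = 3, reps = 5,
                                        seed = 1),
               "seed-sensitive")
})

test_that("reproducibility comparison behaves at the extremes and in calibration", {
  make_rm <- function(vals, alg = "x", reps = 4) {
    m <- matrix(1, reps, reps)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    structure(list(similarity = m, algorithm = alg, k = 2, reps = reps,
                   seeds = seq_len(reps), measure = "rand"),
              class = "rand_matrix")
  }
  same <- make_rm(c(0.5, 0.6, 0.7, 0.6, 0.5, 0.7))
  cmp <- compare_reproducibility(same, same)
  expect_gt(cmp$p.value, 0.9)
  lo <- make_rm(c(0.1, 0.12, 0.11, 0.13, 0.1, 0.12), alg = "low")
  hi <- make_rm(c(0.9, 0.92, 0.91, 0.93, 0.9, 0.92), alg = "high")
  sep <- compare_reproducibility(lo, hi)
  expect_lt(sep$p.value, 0.01)
  expect_equal(sep$lower, "low")
  expect_lt(sep$mean[1], sep$mean[2])

  # calibration: two protocols of the same algorithm on the same data should
  # report similar means and not reject overwhelmingly often. Pairwise values
  # within a protocol are dependent (every run enters reps - 1 pairs), so the
  # p-value over-rejects by design; only loose bounds are asserted, matching
  # the documented pseudo-replication caveat.
  b <- blob_fixture(seed = 137, sd = 3, n_per = 10)
  rejections <- 0L
  mean_gap <- numeric(8)
  for (i in 1:8) {
    r1 <- reproducibility_protocol(b$matrix, "kmeans", k = 4, reps = 6,
                                   seed = derive_seed(1000, paste0("a", i)))
    r2 <- reproducibility_protocol(b$matrix, "kmeans", k = 4, reps = 6,
                                   seed = derive_seed(1000, paste0("b", i)))
    cmp <- compare_reproducibility(r1, r2)
    if (cmp$p.value < 0.05) rejections <- rejections + 1L
    mean_gap[i] <- abs(diff(cmp$mean))
  }
  expect_lte(rejections / 8, 0.5)
  expect_lt(mean(mean_gap), 0.1)
})

test_that("figure of merit has the closed form at k = 1 and flattens at truth", {
  set.seed(139)
  X <- matrix(rnorm(20 * 4, sd = 2), 20, 4)
  fom1 <- figure_of_merit(X, "kmeans", k_range = 1, seed = 2)
  # k = 1: each left-out condition is predicted by its global mean, and the
  # per-condition root mean squared deviations are summed
  expected <- sum(vapply(1:4, function(j) {
    sqrt(mean((X[, j] - mean(X[, j]))^2))
  }, 0))
  expect_equal(fom1$raw, expected, tolerance = 1e-10)
  expect_equal(fom1$value, expected / sqrt((20 - 1) / 20), tolerance = 1e-10)

  b <- blob_fixture(seed = 149)
  fom <- figure_of_merit(b$matrix, "ward", k_range = 1:6)
  # large drop into the true k = 3, little change after
  expect_gt(fom$value[fom$k == 2] - fom$value[fom$k == 3],
            5 * abs(fom$value[fom$k == 3] - fom$value[fom$k == 4]))
})

test_that("Calinski-Harabasz matches the between/within decomposition", {
  set.seed(151)
  X <- matrix(rnorm(30 * 3), 30, 3)
  labels <- sample(3, 30, replace = TRUE)
  k <- length(unique(labels))
  W <- sum(vapply(unique(labels), function(j) {
    sub <- X[labels == j, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
  TSS <- sum(sweep(X, 2, colMeans(X))^2)
  B <- TSS - W
  expect_equal(calinski_harabasz(X, labels),
               (B / (k - 1)) / (W / (30 - k)))
  # degenerate partitions are undefined
  expect_true(is.na(calinski_harabasz(X, rep(1, 30))))
  expect_true(is.na(calinski_harabasz(X[1:3, ], 1:3)))
  # well-separated blobs score higher at the true labeling
  b <- blob_fixture(seed = 157)
  ch_true <- calinski_harabasz(b$matrix$values, b$truth)
  wrong <- b$truth
  wrong[1:10] <- (wrong[1:10] %% 3) + 1
  expect_gt(ch_true, calinski_harabasz(b$matrix$values, wrong))
})

test_that("Index I matches a four-point hand computation", {
  X <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  labels <- c(1, 1, 2, 2)
  # E1 = 4 * sqrt(4.25); Ek = 4 * 0.5 = 2
  # Dk = dist between centers (0, .5) and (4, .5) = 4
  # I = ((1/2) * (E1/Ek) * Dk)^2 = (sqrt(4.25) * 4)^2 = 68
  expect_equal(index_I(X, labels), 68)
  expect_true(is.na(index_I(X, rep(1, 4))))
})

test_that("Davies-Bouldin matches a six-point hand computation", {
  # two 1-D groups, each {-1, 0, 1} around centers 0 and 10
  X <- matrix(c(-1, 0, 1, 9, 10, 11), ncol = 1)
  labels <- c(1, 1, 1, 2, 2, 2)
  # RMS dispersion of each cluster = sqrt(2/3); center distance = 10
  expect_equal(davies_bouldin(X, labels), 2 * sqrt(2 / 3) / 10)
  expect_true(is.na(davies_bouldin(X, rep(1, 6))))
  # lower (better) for the true blobs than for a corrupted labeling
  b <- blob_fixture(seed = 163)
  wrong <- b$truth
  wrong[1:10] <- (wrong[1:10] %% 3) + 1
  expect_lt(davies_bouldin(b$matrix$values, b$truth),
            davies_bouldin(b$matrix$values, wrong))
})

test_that("Krzanowski-Lai difference statistic matches hand values", {
  # constant W, p = 2: DIFF(k) = 10 * ((k-1) - k) = -10 for every k,
  # so every defined KL ratio is 1
  kl <- krzanowski_lai(rep(10, 5), k_values = 2:6, p = 2)
  expect_equal(kl$value[kl$k == 3], 1)
  expect_equal(kl$value[kl$k == 4], 1)
  expect_true(is.na(kl$value[kl$k == 6])) # no k+1 neighbor
  expect_error(krzanowski_lai(rep(1, 3), k_values = c(2, 4, 5), p = 2),
               "consecutive")

  # 1-D two-blob example: the within-SS collapse from k = 1 to k = 2
  # dominates, so KL is maximized at the true k = 2
  X <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), ncol = 1)
  Wk <- vapply(1:4, function(k) {
    if (k == 1) {
      sum((X - mean(X))^2)
    } else {
      labels <- cut_tree(hca(profile_dist(X), "ward"), k)$labels
      sum(vapply(unique(labels), function(j) {
        sub <- X[labels == j, , drop = FALSE]
        sum(sweep(sub, 2, colMeans(sub))^2)
      }, 0))
    }
  }, 0)
  kl2 <- krzanowski_lai(Wk, k_values = 1:4, p = 1)
  ok <- !is.na(kl2$value)
  expect_equal(kl2$k[ok][which.max(kl2$value[ok])], 2L)
})

test_that("index sweeps are deterministic and recover the blob truth", {
  b <- blob_fixture(seed = 167)
  sw1 <- index_sweep(b$matrix, "ward", k_range = 2:8)
  sw2 <- index_sweep(b$matrix, "ward", k_range = 2:8)
  expect_identical(sw1, sw2)
  opt <- vapply(sw1, function(curve) attr(curve, "opt_k"), 0L)
  expect_equal(unname(opt[c("calinski_harabasz", "index_i",
                            "davies_bouldin", "krzanowski_lai")]),
               rep(3L, 4))
  # a length-one sweep cannot form KL second differences
  single <- index_sweep(b$matrix, "ward", k_range = 3,
                        indexes = c("calinski_harabasz", "krzanowski_lai"))
  expect_true(all(is.na(single$krzanowski_lai$value)))
  expect_false(is.na(single$calinski_harabasz$value))
  expect_error(index_sweep(b$matrix, "ward", k_range = 1:3), "k_range")
})

test_that("algorithm similarity matrix is a valid mean-ARI summary", {
  b <- blob_fixture(seed = 173, sd = 2)
  sim <- algorithm_similarity_matrix(
    b$matrix,
    methods = list(ward = list(algorithm = "ward"),
                   kmeans = list(algorithm = "kmeans"),
                   single = list(algorithm = "single")),
    k_range = 2:5, seed = 3
  )
  expect_equal(unname(diag(sim)), rep(1, 3))
  expect_equal(sim, t(sim))
  expect_true(all(sim >= -0.5 & sim <= 1))
  # oracle: recompute one cell directly from the documented seeding convention
  ari <- vapply(2:5, function(k) {
    a <- cluster_profiles(b$matrix, "ward", k,
                          seed = derive_seed(3, paste0("ward:", k)))$labels
    c <- cluster_profiles(b$matrix, "kmeans", k,
                          seed = derive_seed(3, paste0("kmeans:", k)))$labels
    adjusted_rand_index(a, c)
  }, 0)
  expect_equal(sim["ward", "kmeans"], mean(ari))
  # on clearly separated blobs every pair of methods is substantially congruent
  expect_true(all(sim[upper.tri(sim)] > 0.3))
})
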