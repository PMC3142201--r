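## Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stage tag
#'
#' Deterministic integer hash so that every stochastic stage of a run gets
#' its own reproducible seed. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param tag Character tag naming the stage (e.g. `"kmeans:3"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "kmeans:3")
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1, is.finite(master), length(tag) == 1)
  m <- 2147480009 # large prime < 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% m
  as.integer(((abs(as.numeric(master)) %% m) * 92821 + h) %% (m - 1) + 1)
}

## stop() with a consistent prefix for configuration errors
config_error <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

## Squared Euclidean distances between rows of X (n x p) and rows of C (k x p)
rowdist2 <- function(X, C) {
  n2x <- rowSums(X^2)
  n2c <- rowSums(C^2)
  d2 <- outer(n2x, n2c, "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

## cluster centroids; always returns a k x p matrix in label order 1..k
centroids <- function(X, labels, k = max(labels)) {
  p <- ncol(X)
  C <- matrix(NA_real_, k, p)
  for (j in seq_len(k)) {
    idx <- which(labels == j)
    if (length(idx)) C[j, ] <- colMeans(X[idx, , drop = FALSE])
  }
  C
}

## total within-cluster sum of squared Euclidean deviations
within_ss <- function(X, labels) {
  tot <- 0
  for (j in unique(labels)) {
    idx <- which(labels == j)
    cj <- colMeans(X[idx, , drop = FALSE])
    tot <- tot + sum(sweep(X[idx, , drop = FALSE], 2, cj)^2)
  }
  tot
}

total_ss <- function(X) sum(sweep(X, 2, colMeans(X))^2)

## renumber labels so clusters appear as 1, 2, ... in first-appearance order
relabel_first_appearance <- function(labels) {
  match(labels, unique(labels))
}
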