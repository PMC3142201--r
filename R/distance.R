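## Distance measures between protein profiles.

#' Euclidean distance between two profiles
#'
#' Square root of the summed squared coordinate differences — the physical
#' distance between two points in condition space.
#'
#' @param x,y Numeric vectors of equal length (one value per condition).
#' @return Non-negative distance.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("profiles must be finite", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Correlation-based distance between two profiles
#'
#' `d = 1 - r`, with `r` the centered Pearson correlation or the uncentered
#' (cosine) correlation. Ranges over `[0, 2]`: 0 for perfectly correlated
#' profiles, 2 for perfectly anti-correlated ones. Useful when the shape of
#' the regulation pattern matters rather than the ratio level — but note
#' that two profiles at very different abundance levels can then appear
#' similar.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param centered Use centered Pearson correlation (default `TRUE`);
#'   `FALSE` gives the uncentered/cosine form.
#' @return Distance in `[0, 2]`, or `NA` for a zero-variance (centered) or
#'   zero-norm (uncentered) profile.
#' @export
#' @examples
#' correlation_distance(1:4, 2 * (1:4) + 1) # 0
correlation_distance <- function(x, y, centered = TRUE) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("profiles must have length >= 2", call. = FALSE)
  if (centered) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    r <- cor(x, y)
  } else {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(NA_real_)
    r <- sum(x * y) / (nx * ny)
  }
  1 - r
}

#' Pairwise distance matrix over protein profiles
#'
#' @param x A `profile_matrix` or numeric matrix (rows = proteins).
#' @param metric `"euclidean"`, `"pearson"` (centered correlation) or
#'   `"upearson"` (uncentered correlation).
#' @return A `protein_dist`: symmetric matrix `d` with zero diagonal, the
#'   protein `ids` and the `metric` tag.
#' @export
profile_dist <- function(x, metric = c("euclidean", "pearson", "upearson")) {
  metric <- match.arg(metric)
  if (inherits(x, "profile_matrix")) {
    if (!profiles_complete(x)) {
      stop("profile matrix has missing cells; filter or impute first",
           call. = FALSE)
    }
    ids <- x$proteins
    X <- x$values
  } else {
    X <- as.matrix(x)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(X)))
  }
  d <- switch(metric,
    euclidean = as.matrix(dist(X)),
    pearson = 1 - cor(t(X)),
    upearson = {
      nrm <- sqrt(rowSums(X^2))
      nrm[nrm == 0] <- NA_real_
      1 - tcrossprod(X / nrm)
    }
  )
  d[d < 0] <- 0 # guard against negative rounding error
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, ids = ids, metric = metric), class = "protein_dist")
}

#' @export
print.protein_dist <- function(x, ...) {
  cat(sprintf("Protein distance matrix: %d x %d (%s)\n",
              nrow(x$d), ncol(x$d), x$metric))
  invisible(x)
}
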