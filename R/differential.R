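## Per-protein hypothesis testing: one-way ANOVA vs Kruskal-Wallis with
## assumption checks, Holm family-wise error correction, classification,
## concordance and box-whisker summaries.

#' One-way fixed-effects ANOVA on an abundance series
#'
#' Classical one-way decomposition: `F = (SSB/(k-1)) / (SSW/(N-k))` with the
#' p-value from the F distribution on `(k-1, N-k)` degrees of freedom. Each
#' peptide abundance ratio is treated as an independent measurement of the
#' protein's quantity, grouped by condition.
#'
#' Degenerate edges are handled finitely: zero within-group variance with a
#' nonzero between-group component gives `F = Inf`, `p = 0`; an all-constant
#' series gives `F = 0`, `p = 1`. Insufficient data (fewer than 2 groups
#' with 2+ values, or `N <= k`) yields `NA` statistics rather than an error,
#' so the pipeline can mark such proteins untestable.
#'
#' @param values Numeric vector of abundance ratios.
#' @param groups Vector of condition labels, same length as `values`.
#' @return Named numeric vector `c(statistic, p.value)`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4), c("a", "a", "a", "b", "b", "b"))
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- as.character(groups)
  counts <- table(g)
  k <- length(counts)
  N <- length(values)
  if (k < 2 || sum(counts >= 2) < 2 || N <= k) {
    return(c(statistic = NA_real_, p.value = NA_real_))
  }
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ssb <- sum(counts * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(values^2))) {
      return(c(statistic = 0, p.value = 1))
    }
    return(c(statistic = Inf, p.value = 0))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  c(statistic = f, p.value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Kruskal-Wallis rank-sum test on an abundance series
#'
#' Non-parametric alternative to the one-way ANOVA, used when its
#' assumptions (residual normality, variance homogeneity) are in doubt.
#' Tie-corrected H statistic with the p-value from the chi-square
#' distribution on `k - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @inheritParams anova_oneway
#' @return Named numeric vector `c(statistic, p.value)`.
#' @export
#' @examples
#' kruskal_wallis(1:6, rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- as.character(groups)
  counts <- table(g)
  if (length(counts) < 2 || sum(counts >= 2) < 2 ||
      length(values) <= length(counts)) {
    return(c(statistic = NA_real_, p.value = NA_real_))
  }
  if (length(unique(values)) == 1) {
    return(c(statistic = 0, p.value = 1))
  }
  kt <- kruskal.test(values, factor(g))
  c(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Shapiro-Wilk normality check on pooled ANOVA residuals
#'
#' Residuals are each value minus its condition mean, pooled across all
#' conditions ("deviations from the group's mean value should follow a
#' Gaussian distribution"). Requires between 3 and 5000 residuals; outside
#' that range, or for a constant series, returns `NA`.
#'
#' @inheritParams anova_oneway
#' @return A single p-value or `NA`.
#' @export
shapiro_wilk_residuals <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  n <- length(values)
  if (n < 3 || n > 5000) return(NA_real_)
  res <- values - ave(values, as.character(groups))
  if (diff(range(res)) == 0) return(NA_real_)
  tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
}

#' Fligner-Killeen variance-homogeneity check
#'
#' Median-centered normal-scores rank test of equal variances across
#' conditions (via [stats::fligner.test()]); the p-value comes from the
#' chi-square distribution on `k - 1` degrees of freedom. Degenerate input
#' (fewer than 2 groups with 2+ values) returns `NA`.
#'
#' @inheritParams anova_oneway
#' @return A single p-value or `NA`.
#' @export
fligner_killeen <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- factor(as.character(groups))
  counts <- table(g)
  if (length(counts) < 2 || sum(counts >= 2) < 2) return(NA_real_)
  tryCatch({
    p <- fligner.test(values, g)$p.value
    if (is.nan(p)) NA_real_ else p
  }, error = function(e) NA_real_)
}

#' Holm step-down family-wise error correction
#'
#' Sorts p-values ascending, multiplies the i-th by `m - i + 1` (with `m`
#' the number of non-missing values), enforces a monotone non-decreasing
#' cumulative maximum, caps at 1 and restores the input order. `NA` entries
#' are excluded from the family size and stay `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "holm")
  out
}

## classification with explicit precedence (the categories are described in
## terms of the per-family Holm-adjusted p-values at level alpha):
##   strict_significant: ANOVA significant, both assumption checks pass
##   both_lenient: ANOVA significant with violated assumption, corroborated by KW
##   anova_only_assumptions_violated: ANOVA significant with violated
##     assumption, not corroborated by KW
##   kw_only: only KW significant
classify_protein <- function(anova_adj, kw_adj, shapiro_adj, fligner_adj,
                             alpha) {
  if (is.na(anova_adj) && is.na(kw_adj)) return("untestable")
  a_sig <- isTRUE(anova_adj < alpha)
  k_sig <- isTRUE(kw_adj < alpha)
  viol <- isTRUE(shapiro_adj < alpha) || isTRUE(fligner_adj < alpha)
  if (a_sig && !viol) return("strict_significant")
  if (a_sig && viol && k_sig) return("both_lenient")
  if (a_sig && viol) return("anova_only_assumptions_violated")
  if (k_sig) return("kw_only")
  "not_significant"
}

#' Per-protein differential-regulation testing
#'
#' For every protein, pools all peptide abundance ratios into one series
#' grouped by condition and computes four tests: one-way ANOVA,
#' Kruskal-Wallis, Shapiro-Wilk on pooled residuals and Fligner-Killeen.
#' Each test is then Holm-adjusted as its own family across all testable
#' proteins, and a significance classification is assigned at level `alpha`.
#'
#' A protein is testable when at least two conditions carry at least two
#' measurements each and the total measurement count is at least the number
#' of observed conditions plus two; untestable proteins are reported with
#' classification `"untestable"` and excluded from every Holm family.
#' Stored p-values are never capped for display.
#'
#' @param table A [peptide_table()].
#' @param alpha Significance level (default 0.05).
#' @return A `protein_tests` data frame with one row per protein (input
#'   order): `protein`, `n_peptide_hits`, raw p-values `anova_p`, `kw_p`,
#'   `shapiro_p`, `fligner_p`, Holm-adjusted counterparts (`*_adj`), and
#'   `classification`.
#' @export
#' @examples
#' sim <- simulate_peptide_table(simulation_config(n_proteins = 8, seed = 1))
#' res <- run_differential(sim$table)
#' summary(res)
run_differential <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "peptide_table"))
  if (nrow(table) == 0) stop("table is empty", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) config_error("alpha must be in (0, 1)")
  prots <- unique(table$protein)
  idx_by_prot <- split(seq_len(nrow(table)), factor(table$protein, prots))
  n <- length(prots)
  res <- data.frame(
    protein = prots, n_peptide_hits = NA_integer_,
    anova_p = NA_real_, kw_p = NA_real_, shapiro_p = NA_real_,
    fligner_p = NA_real_, stringsAsFactors = FALSE
  )
  testable <- logical(n)
  for (i in seq_len(n)) {
    idx <- idx_by_prot[[i]]
    x <- table$ratio[idx]
    g <- table$condition[idx]
    res$n_peptide_hits[i] <- length(x)
    counts <- base::table(g) # `table` is shadowed by the argument here
    k <- length(counts)
    testable[i] <- k >= 2 && sum(counts >= 2) >= 2 && length(x) >= k + 2
    if (!testable[i]) next
    a <- anova_oneway(x, g)
    kw <- kruskal_wallis(x, g)
    res$anova_p[i] <- a[["p.value"]]
    res$kw_p[i] <- kw[["p.value"]]
    res$shapiro_p[i] <- shapiro_wilk_residuals(x, g)
    res$fligner_p[i] <- fligner_killeen(x, g)
  }
  ## Holm per family, across testable proteins only
  for (col in c("anova_p", "kw_p", "shapiro_p", "fligner_p")) {
    adj <- rep(NA_real_, n)
    adj[testable] <- holm_adjust(res[[col]][testable])
    res[[paste0(col, "_adj")]] <- adj
  }
  res$classification <- vapply(seq_len(n), function(i) {
    if (!testable[i]) return("untestable")
    classify_protein(res$anova_p_adj[i], res$kw_p_adj[i],
                     res$shapiro_p_adj[i], res$fligner_p_adj[i], alpha)
  }, character(1))
  attr(res, "alpha") <- alpha
  class(res) <- c("protein_tests", "data.frame")
  res
}

#' @export
print.protein_tests <- function(x, ...) {
  cat(sprintf("Protein differential tests: %d proteins (alpha = %g)\n",
              nrow(x), attr(x, "alpha")))
  print(table(x$classification))
  invisible(x)
}

#' @export
summary.protein_tests <- function(object, ...) {
  alpha <- attr(object, "alpha")
  cls <- table(factor(object$classification,
                      c("strict_significant", "both_lenient",
                        "anova_only_assumptions_violated", "kw_only",
                        "not_significant", "untestable")))
  out <- list(alpha = alpha, n = nrow(object), classification = cls,
              n_anova_sig = sum(object$anova_p_adj < alpha, na.rm = TRUE),
              n_kw_sig = sum(object$kw_p_adj < alpha, na.rm = TRUE))
  class(out) <- "summary.protein_tests"
  out
}

#' @export
print.summary.protein_tests <- function(x, ...) {
  cat(sprintf("%d proteins tested at alpha = %g\n", x$n, x$alpha))
  cat(sprintf("ANOVA-significant (Holm): %d;  KW-significant (Holm): %d\n",
              x$n_anova_sig, x$n_kw_sig))
  print(x$classification)
  invisible(x)
}

#' Concordance between ANOVA and Kruskal-Wallis results
#'
#' Spearman rank correlation (average ranks for ties) between the raw ANOVA
#' and KW p-value vectors, plus overlap counts of the Holm-adjusted calls.
#' Raw p-values are used because the step-down adjustment introduces ties
#' that would distort the ranks.
#'
#' @param results A `protein_tests` object from [run_differential()].
#' @param alpha Significance level; defaults to the one stored in `results`.
#' @return A `concordance_summary` list: `spearman_rho`, `n_anova_sig`,
#'   `n_kw_sig`, `n_strict`, `n_overlap_lenient`, `n_tested`.
#' @export
concordance <- function(results, alpha = attr(results, "alpha")) {
  stopifnot(inherits(results, "protein_tests"))
  ok <- !is.na(results$anova_p) & !is.na(results$kw_p)
  rho <- if (sum(ok) >= 3) {
    cor(results$anova_p[ok], results$kw_p[ok], method = "spearman")
  } else {
    NA_real_
  }
  out <- list(
    spearman_rho = rho,
    n_anova_sig = sum(results$anova_p_adj < alpha, na.rm = TRUE),
    n_kw_sig = sum(results$kw_p_adj < alpha, na.rm = TRUE),
    n_strict = sum(results$classification == "strict_significant"),
    n_overlap_lenient = sum(results$anova_p_adj < alpha &
                              results$kw_p_adj < alpha, na.rm = TRUE),
    n_tested = sum(ok)
  )
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "Spearman rho (raw ANOVA vs KW p-values): %.4f over %d proteins\n",
    x$spearman_rho, x$n_tested))
  cat(sprintf(
    "ANOVA-significant: %d  KW-significant: %d  strict: %d  lenient overlap: %d\n",
    x$n_anova_sig, x$n_kw_sig, x$n_strict, x$n_overlap_lenient))
  invisible(x)
}

#' Box-whisker summary of an abundance series per condition
#'
#' The five characteristics of each condition's measurements: median, lower
#' and upper quartiles (linear interpolation between order statistics,
#' `type = 7`), and whiskers at the most extreme data points within
#' 1.5 IQR of the quartiles; points beyond the whiskers are listed as
#' outliers.
#'
#' @inheritParams anova_oneway
#' @return A `boxplot_summary` data frame with one row per condition
#'   (`group`, `n`, `whisker_low`, `q1`, `median`, `q3`, `whisker_high`,
#'   `n_outliers`) and an `outliers` attribute (named list of outlying
#'   values per group).
#' @export
#' @examples
#' boxplot_summary(c(1, 2, 3, 4, 5, 100), rep("a", 6))
boxplot_summary <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- as.character(groups)
  labs <- unique(g)
  rows <- vector("list", length(labs))
  outs <- vector("list", length(labs))
  names(outs) <- labs
  for (i in seq_along(labs)) {
    x <- values[g == labs[i]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    wl <- min(inside)
    wh <- max(inside)
    out_vals <- x[x < wl | x > wh]
    rows[[i]] <- data.frame(
      group = labs[i], n = length(x), whisker_low = wl, q1 = q[1],
      median = q[2], q3 = q[3], whisker_high = wh,
      n_outliers = length(out_vals), stringsAsFactors = FALSE
    )
    outs[[i]] <- out_vals
  }
  res <- do.call(rbind, rows)
  attr(res, "outliers") <- outs
  class(res) <- c("boxplot_summary", "data.frame")
  res
}
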