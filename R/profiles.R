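## Protein profiles: aggregate peptide ratios to one value per protein and
## condition, filter by measurement support, optionally impute.

new_profile_matrix <- function(values, support, missing, imputed, proteins,
                               conditions, min_support, statistic = "mean") {
  stopifnot(
    identical(dim(values), dim(support)),
    identical(dim(values), dim(missing)),
    identical(dim(values), dim(imputed)),
    nrow(values) == length(proteins),
    ncol(values) == length(conditions)
  )
  structure(list(values = values, support = support, missing = missing,
                 imputed = imputed, proteins = proteins,
                 conditions = conditions,
                 min_support = as.integer(min_support),
                 statistic = statistic),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "Protein profile matrix: %d proteins x %d conditions (%s, min support %d)\n",
    length(x$proteins), length(x$conditions), x$statistic, x$min_support))
  if (any(x$missing)) {
    cat(sprintf("  %d missing cells (%d imputed)\n", sum(x$missing),
                sum(x$imputed)))
  }
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' @export
as.matrix.profile_matrix <- function(x, ...) x$values

#' Aggregate peptide ratios to a protein profile matrix
#'
#' Forms one value per protein and condition by averaging all peptide
#' abundance ratios for that cell (arithmetic mean by default; median or
#' trimmed mean optionally). Cells with fewer than `min_support`
#' measurements are flagged missing; by default, proteins with any missing
#' cell are excluded so that every retained protein has at least
#' `min_support` peptide measurements per condition. Set `filter = FALSE`
#' to keep all proteins with the missing mask set (the input to
#' [impute_profiles()]).
#'
#' @param table A [peptide_table()].
#' @param min_support Minimum peptide measurements per protein-condition
#'   cell (default 2).
#' @param statistic One of `"mean"`, `"median"`, `"trimmed"`.
#' @param trim Trim fraction for `statistic = "trimmed"` (default 0.1).
#' @param filter Exclude proteins with any under-supported condition
#'   (default `TRUE`).
#' @return A `profile_matrix`: values, support counts, missing and imputed
#'   masks, protein and condition order.
#' @export
#' @examples
#' sim <- simulate_peptide_table(simulation_config(n_proteins = 6, seed = 3))
#' aggregate_profiles(sim$table)
aggregate_profiles <- function(table, min_support = 2,
                               statistic = c("mean", "median", "trimmed"),
                               trim = 0.1, filter = TRUE) {
  stopifnot(inherits(table, "peptide_table"))
  statistic <- match.arg(statistic)
  if (!is_count(min_support, 1)) config_error("min_support must be >= 1")
  prots <- unique(table$protein)
  conds <- conditions(table)
  np <- length(prots)
  nc <- length(conds)
  agg_fun <- switch(statistic,
    mean = mean,
    median = median,
    trimmed = function(x) mean(x, trim = trim)
  )
  values <- matrix(NA_real_, np, nc, dimnames = list(prots, conds))
  support <- matrix(0L, np, nc, dimnames = list(prots, conds))
  if (np > 0) {
    fp <- factor(table$protein, prots)
    fc <- factor(table$condition, conds)
    cnt <- base::table(fp, fc)
    support[] <- as.integer(cnt)
    means <- tapply(table$ratio, list(fp, fc), agg_fun)
    values[] <- means
  }
  missing <- support < min_support
  pm <- new_profile_matrix(values, support, missing,
                           imputed = matrix(FALSE, np, nc,
                                            dimnames = list(prots, conds)),
                           proteins = prots, conditions = conds,
                           min_support = min_support, statistic = statistic)
  if (filter) pm <- subset_profiles(pm, !apply(missing, 1, any)) else pm
}

## row-subset a profile matrix, preserving all masks
subset_profiles <- function(pm, keep) {
  new_profile_matrix(
    pm$values[keep, , drop = FALSE], pm$support[keep, , drop = FALSE],
    pm$missing[keep, , drop = FALSE], pm$imputed[keep, , drop = FALSE],
    pm$proteins[keep], pm$conditions, pm$min_support, pm$statistic
  )
}

#' Impute missing profile cells with the protein's mean over conditions
#'
#' Replaces each missing cell by that protein's mean abundance ratio over
#' its observed conditions, keeping proteins with at most
#' `max_missing_per_protein` missing cells and at least one observed cell;
#' the rest are dropped (with a warning reporting the count). Observed cells
#' are never altered, and imputed cells are flagged in the `imputed` mask.
#'
#' @param pm A `profile_matrix` built with `filter = FALSE`.
#' @param max_missing_per_protein Missing-cell budget per protein
#'   (default 1).
#' @return A `profile_matrix` with no unfilled missing cells.
#' @export
impute_profiles <- function(pm, max_missing_per_protein = 1) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!is_count(max_missing_per_protein)) {
    config_error("max_missing_per_protein must be a count >= 0")
  }
  n_miss <- rowSums(pm$missing)
  nc <- length(pm$conditions)
  keep <- n_miss <= max_missing_per_protein & n_miss < nc
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warning(sprintf("dropping %d protein(s) exceeding the missing budget",
                    n_drop), call. = FALSE)
  }
  out <- subset_profiles(pm, keep)
  miss <- out$missing
  if (any(miss)) {
    for (i in which(rowSums(miss) > 0)) {
      obs <- !miss[i, ]
      out$values[i, !obs] <- mean(out$values[i, obs])
      out$imputed[i, !obs] <- TRUE
    }
  }
  out
}

## TRUE when every cell is usable for clustering (observed or imputed)
profiles_complete <- function(pm) {
  !any(pm$missing & !pm$imputed) && !anyNA(pm$values)
}
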