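## Core data types and tab-separated input/output.

#' Construct a peptide quantification table
#'
#' Long-format table of peptide-level 15N/14N abundance ratios. Each row is
#' one measurement of one peptide of one protein under one condition and
#' replicate. The ordered set of condition labels is fixed at construction
#' and preserved through every downstream stage. Length-one arguments are
#' recycled to the table length.
#'
#' @param protein Character vector of protein accessions.
#' @param peptide Character vector of peptide identifiers.
#' @param condition Character vector of condition labels (time points or
#'   carbon sources); must be non-empty strings.
#' @param replicate Character vector of replicate labels; non-empty.
#' @param ratio Numeric vector of positive, finite labeled/unlabeled
#'   abundance ratios.
#' @param conditions Optional character vector fixing the condition order;
#'   defaults to first-appearance order. Every condition in the data must
#'   appear in it.
#' @return A `peptide_table`: a `data.frame` with columns `protein`,
#'   `peptide`, `condition`, `replicate`, `ratio` and a `conditions`
#'   attribute holding the ordered condition labels.
#' @export
#' @examples
#' pt <- peptide_table(
#'   protein = c("P1", "P1"), peptide = c("a", "b"),
#'   condition = c("t0", "t1"), replicate = c("r1", "r1"),
#'   ratio = c(1.2, 0.8)
#' )
#' conditions(pt)
peptide_table <- function(protein, peptide, condition, replicate, ratio,
                          conditions = NULL) {
  protein <- as.character(protein)
  peptide <- as.character(peptide)
  condition <- as.character(condition)
  replicate <- as.character(replicate)
  ratio <- as.numeric(ratio)
  n <- max(length(protein), length(peptide), length(condition),
           length(replicate), length(ratio))
  recycle <- function(x) if (length(x) == 1 && n > 1) rep(x, n) else x
  protein <- recycle(protein)
  peptide <- recycle(peptide)
  condition <- recycle(condition)
  replicate <- recycle(replicate)
  ratio <- recycle(ratio)
  if (length(protein) != n || length(peptide) != n ||
      length(condition) != n || length(replicate) != n ||
      length(ratio) != n) {
    stop("all columns must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (any(!nzchar(condition)) || any(is.na(condition))) {
      stop("condition labels must be non-empty", call. = FALSE)
    }
    if (any(!nzchar(replicate)) || any(is.na(replicate))) {
      stop("replicate labels must be non-empty", call. = FALSE)
    }
    bad <- which(!is.finite(ratio) | ratio <= 0)
    if (length(bad)) {
      stop(sprintf("ratio must be positive and finite (first bad row: %d)",
                   bad[1]), call. = FALSE)
    }
  }
  if (is.null(conditions)) conditions <- unique(condition)
  conditions <- as.character(conditions)
  if (n > 0 && !all(condition %in% conditions)) {
    stop("every record's condition must appear in the condition list",
         call. = FALSE)
  }
  out <- data.frame(
    protein = protein, peptide = peptide, condition = condition,
    replicate = replicate, ratio = ratio, stringsAsFactors = FALSE
  )
  attr(out, "conditions") <- conditions
  class(out) <- c("peptide_table", "data.frame")
  out
}

#' Ordered condition labels of a table or matrix
#'
#' @param x A [peptide_table()] or `profile_matrix` object.
#' @return Character vector of condition labels in pipeline order.
#' @export
conditions <- function(x) {
  if (inherits(x, "profile_matrix")) return(x$conditions)
  attr(x, "conditions")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf(
    "Peptide quantification table: %d measurements, %d proteins, %d conditions (%s)\n",
    nrow(x), length(unique(x$protein)), length(conditions(x)),
    paste(conditions(x), collapse = ", ")
  ))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a peptide quantification table from a TSV file
#'
#' Expects a tab-separated file with a header naming five columns (protein,
#' peptide, condition, replicate, ratio). External exports with different
#' column names can be mapped via `dialect` without rewriting files.
#'
#' @param path Path to a tab-separated file.
#' @param dialect Named character vector mapping the canonical names
#'   `protein`, `peptide`, `condition`, `replicate`, `ratio` to the column
#'   names used in the file.
#' @param conditions Optional condition order override; default is
#'   first-appearance order in the file.
#' @param log_transform If `TRUE`, ratios are log2-transformed once at load
#'   time (recorded in the `log_transform` attribute). Default `FALSE`:
#'   ratios are analyzed as given.
#' @return A [peptide_table()].
#' @export
read_peptide_table <- function(path,
                               dialect = c(protein = "protein",
                                           peptide = "peptide",
                                           condition = "condition",
                                           replicate = "replicate",
                                           ratio = "ratio"),
                               conditions = NULL,
                               log_transform = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  need <- c("protein", "peptide", "condition", "replicate", "ratio")
  full <- c(protein = "protein", peptide = "peptide", condition = "condition",
            replicate = "replicate", ratio = "ratio")
  full[names(dialect)] <- dialect
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   comment.char = "#")
  for (canon in need) {
    if (!full[[canon]] %in% names(df)) {
      stop(sprintf("missing required column '%s' in %s", full[[canon]], path),
           call. = FALSE)
    }
  }
  if (nrow(df) == 0) {
    return(peptide_table(character(), character(), character(), character(),
                         numeric(), conditions = conditions))
  }
  ratio <- suppressWarnings(as.numeric(df[[full[["ratio"]]]]))
  bad <- which(is.na(ratio) | !is.finite(ratio) | ratio <= 0)
  if (length(bad)) {
    stop(sprintf(
      "invalid ratio '%s' at line %d of %s (must be a positive number)",
      df[[full[["ratio"]]]][bad[1]], bad[1] + 1L, path
    ), call. = FALSE)
  }
  if (log_transform) ratio <- log2(ratio)
  tab <- data.frame(
    protein = df[[full[["protein"]]]], peptide = df[[full[["peptide"]]]],
    condition = df[[full[["condition"]]]],
    replicate = df[[full[["replicate"]]]], ratio = ratio,
    stringsAsFactors = FALSE
  )
  if (log_transform) {
    # bypass the ratio > 0 check, which applies to the raw scale
    out <- tab
    attr(out, "conditions") <- if (is.null(conditions)) unique(tab$condition) else conditions
    class(out) <- c("peptide_table", "data.frame")
  } else {
    out <- peptide_table(tab$protein, tab$peptide, tab$condition,
                         tab$replicate, tab$ratio, conditions = conditions)
  }
  attr(out, "log_transform") <- log_transform
  out
}

#' Write a tabular result as TSV
#'
#' Tab-separated output with one header line and a deterministic column
#' order; numeric columns are serialized with 6 significant digits, so two
#' writes of the same data are byte-identical.
#'
#' @param x A data frame (any pipeline result table) or a `profile_matrix`
#'   (written in wide format, one column per condition).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.6g", out[[j]]))
    }
  }
  con <- file(path, open = "wb") # binary mode: identical bytes on rewrite
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @export
write_table.profile_matrix <- function(x, path) {
  df <- data.frame(protein = x$proteins, stringsAsFactors = FALSE)
  vals <- x$values
  for (j in seq_along(x$conditions)) df[[x$conditions[j]]] <- vals[, j]
  write_table(df, path)
}

#' Analysis configuration
#'
#' Bundles the shared knobs of the pipeline: significance level, optional
#' log transform, minimum per-condition peptide support, the cluster-number
#' sweep range, and the master seed.
#'
#' @param alpha Significance level in (0, 1); 0.05 and 0.01 are common.
#' @param log_transform Apply log2 at load time (default `FALSE`).
#' @param min_peptides_per_condition Minimum peptide measurements per
#'   protein and condition for profile inclusion (default 2).
#' @param k_min,k_max Cluster-number sweep bounds (`k_min >= 2`).
#' @param seed Master integer seed for all randomness.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, log_transform = FALSE,
                            min_peptides_per_condition = 2,
                            k_min = 2, k_max = 10, seed = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    config_error("alpha must be in (0, 1)")
  }
  if (!is_count(min_peptides_per_condition, min = 1)) {
    config_error("min_peptides_per_condition must be an integer >= 1")
  }
  if (!is_count(k_min, min = 2)) config_error("k_min must be an integer >= 2")
  if (!is_count(k_max, min = k_min)) config_error("k_max must be >= k_min")
  if (!is_count(abs(seed))) config_error("seed must be an integer")
  structure(list(alpha = alpha, log_transform = isTRUE(log_transform),
                 min_peptides_per_condition = as.integer(min_peptides_per_condition),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML key-value file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  yaml::read_yaml(path)
}
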