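## End-to-end orchestration: simulate/load -> test -> aggregate -> cluster ->
## validate, with per-stage TSV outputs and a run manifest.

#' Run the full evaluation pipeline
#'
#' Executes the recommended workflow end to end: obtain a peptide table
#' (simulated from `config$simulate`, or read from `config$input`), run the
#' per-protein differential tests (ANOVA with assumption checks plus
#' Kruskal-Wallis, Holm-corrected), aggregate peptide ratios to protein
#' profiles, cluster the profiles (default: Ward/Euclidean hierarchical plus
#' neural gas, the two recommended algorithms), and validate cluster numbers
#' with the validity-index sweep and the stochastic-algorithm
#' reproducibility protocol. Every stage writes its TSV outputs under
#' `output_dir` and is driven by seeds derived from the master seed, so two
#' runs with the same configuration produce identical files.
#'
#' @param config A named list or the path to a YAML file. Recognized keys
#'   (all optional): `simulate` (arguments for [simulation_config()]),
#'   `input` (peptide TSV path, used when `simulate` is absent), `alpha`,
#'   `min_support`, `statistic`, `cluster` (list: `algorithm`, `distance`,
#'   `k`), `validate` (list: `k_min`, `k_max`, `protocol_k`, `reps`),
#'   `seed`.
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Master seed override.
#' @return A `run_manifest` list: config snapshot, seeds, per-stage record
#'   counts, output file paths, and the summary report (significant-protein
#'   counts per classification, concordance, selected `k` per index, and the
#'   recommended clusterings).
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(
#'   list(simulate = list(n_proteins = 20), seed = 7),
#'   output_dir = tempfile("run")
#' )
#' man$counts
#' }
run_pipeline <- function(config = list(), output_dir = "pepratio_run",
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  master <- as.integer(config$seed)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  min_support <- if (is.null(config$min_support)) 2L else config$min_support
  statistic <- if (is.null(config$statistic)) "mean" else config$statistic
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  out_file <- function(name) {
    f <- file.path(output_dir, name)
    files[[name]] <<- f
    f
  }
  counts <- list()

  ## stage 1: obtain peptide table ---------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- derive_seed(master, "simulate")
    sim <- simulate_peptide_table(do.call(simulation_config, sim_args))
    tab <- sim$table
    truth <- sim$truth
    write_table(as.data.frame(tab), out_file("peptides.tsv"))
    write_table(truth, out_file("truth.tsv"))
  } else if (!is.null(config$input)) {
    tab <- read_peptide_table(config$input,
                              log_transform = isTRUE(config$log_transform))
  } else {
    config_error("config needs either a 'simulate' section or an 'input' path")
  }
  counts$peptide_records <- nrow(tab)
  counts$proteins_quantified <- length(unique(tab$protein))
  if (nrow(tab) == 0) config_error("no peptide records to analyze")

  ## stage 2: differential testing ---------------------------------------
  tests <- run_differential(tab, alpha = alpha)
  write_table(as.data.frame(tests), out_file("protein_tests.tsv"))
  counts$proteins_testable <- sum(tests$classification != "untestable")
  conc <- concordance(tests)
  write_table(data.frame(
    spearman_rho = conc$spearman_rho, n_anova_sig = conc$n_anova_sig,
    n_kw_sig = conc$n_kw_sig, n_strict = conc$n_strict,
    n_overlap_lenient = conc$n_overlap_lenient, n_tested = conc$n_tested
  ), out_file("concordance.tsv"))

  ## stage 3: aggregation -------------------------------------------------
  pm <- aggregate_profiles(tab, min_support = min_support,
                           statistic = statistic)
  write_table(pm, out_file("profiles.tsv"))
  supp <- data.frame(protein = pm$proteins, stringsAsFactors = FALSE)
  for (j in seq_along(pm$conditions)) supp[[pm$conditions[j]]] <- pm$support[, j]
  write_table(supp, out_file("support.tsv"))
  counts$proteins_clustered <- length(pm$proteins)

  ## stage 4: clustering --------------------------------------------------
  ccfg <- if (is.null(config$cluster)) list() else config$cluster
  algorithm <- if (is.null(ccfg$algorithm)) "ward" else ccfg$algorithm
  distance <- if (is.null(ccfg$distance)) "euclidean" else ccfg$distance
  n <- length(pm$proteins)
  if (n < 4) config_error("too few proteins pass the support filter (%d)", n)
  k <- if (is.null(ccfg$k)) max(2L, min(20L, n %/% 4L)) else ccfg$k
  primary <- cluster_profiles(pm, algorithm, k, distance = distance,
                              seed = derive_seed(master, "cluster:primary"))
  write_table(data.frame(protein = pm$proteins, cluster = primary$labels),
              out_file("labels.tsv"))
  if (!is.null(primary$centers)) {
    cdf <- as.data.frame(primary$centers)
    names(cdf) <- pm$conditions
    cdf <- cbind(data.frame(cluster = seq_len(nrow(cdf))), cdf)
    write_table(cdf, out_file("centers.tsv"))
  }
  secondary <- cluster_profiles(pm, "neuralgas", k,
                                seed = derive_seed(master, "cluster:ng"))
  write_table(data.frame(protein = pm$proteins,
                         cluster = secondary$labels),
              out_file("labels_neuralgas.tsv"))
  tree <- hca(profile_dist(pm, "euclidean"), "ward")
  curve <- merge_distance_curve(tree)
  write_table(curve, out_file("merge_curve.tsv"))

  ## stage 5: validation --------------------------------------------------
  vcfg <- if (is.null(config$validate)) list() else config$validate
  k_min <- if (is.null(vcfg$k_min)) 2L else vcfg$k_min
  k_max <- if (is.null(vcfg$k_max)) min(10L, n - 1L) else vcfg$k_max
  k_max <- min(k_max, n - 1L)
  sweep_res <- index_sweep(pm, algorithm, k_min:k_max,
                           indexes = c("calinski_harabasz", "index_i",
                                       "davies_bouldin", "krzanowski_lai"),
                           seed = derive_seed(master, "sweep"),
                           distance = distance)
  curves <- do.call(rbind, lapply(names(sweep_res), function(nm) {
    ic <- sweep_res[[nm]]
    data.frame(index = nm, k = ic$k, value = ic$value,
               optimum = !is.na(attr(ic, "opt_k")) & ic$k == attr(ic, "opt_k"),
               stringsAsFactors = FALSE)
  }))
  write_table(curves, out_file("index_curves.tsv"))
  selected_k <- vapply(sweep_res, function(ic) as.integer(attr(ic, "opt_k")),
                       integer(1))

  reps <- if (is.null(vcfg$reps)) 10L else vcfg$reps
  protocol_k <- if (is.null(vcfg$protocol_k)) min(20L, n - 1L) else vcfg$protocol_k
  rm_km <- reproducibility_protocol(pm, "kmeans", k = protocol_k, reps = reps,
                                    seed = derive_seed(master, "protocol"))
  rm_ng <- reproducibility_protocol(pm, "neuralgas", k = protocol_k,
                                    reps = reps,
                                    seed = derive_seed(master, "protocol"))
  cmp <- compare_reproducibility(rm_km, rm_ng)
  write_table(as.data.frame(rm_km$similarity), out_file("rand_matrix_kmeans.tsv"))
  write_table(as.data.frame(rm_ng$similarity), out_file("rand_matrix_neuralgas.tsv"))
  write_table(data.frame(
    algorithm = cmp$algorithms, mean_similarity = cmp$mean, sd = cmp$sd,
    p_value = cmp$p.value, lower = cmp$lower == cmp$algorithms
  ), out_file("comparison.tsv"))

  ## summary --------------------------------------------------------------
  cls <- base::table(tests$classification)
  summary_df <- data.frame(
    metric = c(paste0("n_", names(cls)), "spearman_rho",
               paste0("selected_k_", names(selected_k)),
               "merge_curve_knee", "reproducibility_lower"),
    value = c(as.character(as.integer(cls)),
              sprintf("%.6g", conc$spearman_rho),
              as.character(selected_k),
              as.character(attr(curve, "knee")), cmp$lower),
    stringsAsFactors = FALSE
  )
  write_table(summary_df, out_file("summary.tsv"))

  manifest <- list(
    config = config, seed = master,
    stage_seeds = c(simulate = derive_seed(master, "simulate"),
                    cluster = derive_seed(master, "cluster:primary"),
                    sweep = derive_seed(master, "sweep"),
                    protocol = derive_seed(master, "protocol")),
    counts = counts, files = files,
    summary = list(classification = cls,
                   spearman_rho = conc$spearman_rho,
                   selected_k = selected_k,
                   merge_curve_knee = attr(curve, "knee"),
                   reproducibility = cmp,
                   recommended = c("ward/euclidean", "neuralgas")),
    version = as.character(utils::packageVersion("pepratio"))
  )
  class(manifest) <- "run_manifest"
  yaml::write_yaml(list(seed = master, counts = counts,
                        files = as.list(files),
                        version = manifest$version),
                   file.path(output_dir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pepratio pipeline run\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  peptide records: %d; proteins quantified: %d; testable: %d; clustered: %d\n",
              x$counts$peptide_records, x$counts$proteins_quantified,
              x$counts$proteins_testable, x$counts$proteins_clustered))
  cat(sprintf("  Spearman rho (ANOVA vs KW): %.4f\n", x$summary$spearman_rho))
  cat(sprintf("  selected k: %s\n",
              paste(sprintf("%s=%s", names(x$summary$selected_k),
                            x$summary$selected_k), collapse = ", ")))
  cat(sprintf("  lower reproducibility: %s\n", x$summary$reproducibility$lower))
  cat(sprintf("  %d output files in place\n", length(x$files)))
  invisible(x)
}
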