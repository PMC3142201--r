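## Synthetic-data generator: peptide tables and profile matrices with the
## statistical structure the analysis assumes, plus ground truth.

#' Simulation configuration for synthetic peptide tables
#'
#' Defaults emulate a replicated bacterial time-course experiment: five
#' conditions measured in three biological replicates, with ten peptide
#' abundance ratios per protein and condition, Gaussian measurement noise on
#' the ratio scale, and configurable fractions of regulated proteins,
#' assumption violators (heteroscedastic or heavy-tailed), under-supported
#' protein-condition cells, and label-swap contaminants that produce both
#' very high and very low ratios.
#'
#' @param n_proteins Number of simulated proteins.
#' @param conditions Ordered condition labels (default five time points).
#' @param replicates Number of replicates per condition (default 3).
#' @param peptides_per_condition Peptide measurements per protein and
#'   condition, pooled over replicates (default 10).
#' @param frac_regulated Fraction of proteins with condition-dependent mean
#'   profiles (default 0.2).
#' @param effect_size Mean-shift magnitude between conditions for regulated
#'   proteins, in ratio units (default 1).
#' @param baseline_range Range of per-protein baseline ratios, drawn
#'   uniformly (default `c(0.8, 1.2)`).
#' @param noise_sd Measurement noise standard deviation on the ratio scale
#'   (default 0.25).
#' @param frac_heteroscedastic Fraction of proteins with one condition's
#'   noise SD multiplied by `hetero_factor` (default 0).
#' @param hetero_factor Variance-violation SD multiplier (default 4).
#' @param frac_heavy_tailed Fraction of proteins with scaled t(3) residuals
#'   instead of Gaussian (default 0).
#' @param missing_rate Fraction of protein-by-condition cells receiving
#'   fewer than two peptide measurements (default 0).
#' @param frac_contaminant Fraction of proteins whose measurements carry a
#'   random label-swap factor (x5 or /5), yielding extreme variance
#'   (default 0).
#' @param seed Integer seed; identical configs give identical tables.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 100,
                              conditions = c("t0", "t10", "t30", "t60", "t120"),
                              replicates = 3,
                              peptides_per_condition = 10,
                              frac_regulated = 0.2,
                              effect_size = 1,
                              baseline_range = c(0.8, 1.2),
                              noise_sd = 0.25,
                              frac_heteroscedastic = 0,
                              hetero_factor = 4,
                              frac_heavy_tailed = 0,
                              missing_rate = 0,
                              frac_contaminant = 0,
                              seed = 1) {
  if (!is_count(n_proteins)) config_error("n_proteins must be a count >= 0")
  if (length(conditions) < 2) config_error("need at least 2 conditions")
  if (!is_count(replicates, 1)) config_error("replicates must be >= 1")
  if (!is_count(peptides_per_condition, 1)) {
    config_error("peptides_per_condition must be >= 1")
  }
  for (f in c(frac_regulated, frac_heteroscedastic, frac_heavy_tailed,
              missing_rate, frac_contaminant)) {
    if (!is_fraction(f)) config_error("fractions must lie in [0, 1]")
  }
  if (frac_heteroscedastic + frac_heavy_tailed > 1) {
    config_error("violation fractions must sum to at most 1")
  }
  if (!is.finite(effect_size)) config_error("effect_size must be finite")
  if (!is.numeric(noise_sd) || noise_sd <= 0) config_error("noise_sd must be > 0")
  structure(list(
    n_proteins = as.integer(n_proteins),
    conditions = as.character(conditions),
    replicates = as.integer(replicates),
    peptides_per_condition = as.integer(peptides_per_condition),
    frac_regulated = frac_regulated, effect_size = effect_size,
    baseline_range = baseline_range, noise_sd = noise_sd,
    frac_heteroscedastic = frac_heteroscedastic, hetero_factor = hetero_factor,
    frac_heavy_tailed = frac_heavy_tailed, missing_rate = missing_rate,
    frac_contaminant = frac_contaminant, seed = as.integer(seed)
  ), class = "simulation_config")
}

## condition-profile shapes for regulated proteins, each standardized to
## max |shift| = 1: an abrupt step, a monotone ramp, and a transient pulse
## (mimicking e.g. down-regulation after 30 min or steady increase over time)
profile_shape <- function(shape, n_cond, changepoint) {
  s <- switch(shape,
    step  = c(rep(0, changepoint), rep(1, n_cond - changepoint)),
    ramp  = seq(0, 1, length.out = n_cond),
    pulse = {
      v <- rep(0, n_cond)
      v[changepoint] <- 1
      v
    }
  )
  s - mean(s)
}

#' Simulate a peptide quantification table with ground truth
#'
#' Unregulated proteins draw all measurements from one condition-independent
#' distribution around the protein's baseline ratio. Regulated proteins
#' receive a condition-dependent mean profile (step, ramp or pulse shape,
#' random sign) of magnitude `effect_size`. Violation fractions are realized
#' as disjoint protein sets: heteroscedastic proteins get one condition's SD
#' multiplied, heavy-tailed proteins get scaled t(3) residuals.
#' Contaminants (emulating a 15N/14N label swap) multiply each measurement
#' by 5 or 1/5 at random. Cells selected for missingness receive fewer than
#' two peptide measurements, so they fall below the default support filter.
#' Ratios are floored at `1e-6` to respect positivity.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `table` (a [peptide_table()]) and `truth`
#'   (a data frame with one row per protein: `protein`, `regulated`,
#'   `shape`, `violation` in `none/variance/normality`, `contaminant`,
#'   and `n_missing_cells`).
#' @export
#' @examples
#' sim <- simulate_peptide_table(simulation_config(n_proteins = 5, seed = 42))
#' sim$truth
simulate_peptide_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  np <- cfg$n_proteins
  conds <- cfg$conditions
  nc <- length(conds)
  if (np == 0) {
    return(list(
      table = peptide_table(character(), character(), character(),
                            character(), numeric(), conditions = conds),
      truth = data.frame(protein = character(), regulated = logical(),
                         shape = character(), violation = character(),
                         contaminant = logical(),
                         n_missing_cells = integer(),
                         stringsAsFactors = FALSE)
    ))
  }
  set.seed(cfg$seed)
  prot <- sprintf("PROT%05d", seq_len(np))

  regulated <- rep(FALSE, np)
  n_reg <- round(cfg$frac_regulated * np)
  if (n_reg > 0) regulated[sample(np, n_reg)] <- TRUE
  shapes <- rep(NA_character_, np)
  shapes[regulated] <- sample(c("step", "ramp", "pulse"), n_reg, replace = TRUE)

  violation <- rep("none", np)
  n_var <- round(cfg$frac_heteroscedastic * np)
  n_tail <- round(cfg$frac_heavy_tailed * np)
  if (n_var + n_tail > 0) {
    viol_idx <- sample(np, n_var + n_tail)
    if (n_var > 0) violation[viol_idx[seq_len(n_var)]] <- "variance"
    if (n_tail > 0) violation[viol_idx[n_var + seq_len(n_tail)]] <- "normality"
  }
  contaminant <- rep(FALSE, np)
  clean <- which(violation == "none")
  n_cont <- round(cfg$frac_contaminant * np)
  if (n_cont > 0) contaminant[sample(clean, min(n_cont, length(clean)))] <- TRUE

  baseline <- runif(np, cfg$baseline_range[1], cfg$baseline_range[2])

  ## per-protein condition mean matrix
  mu <- matrix(baseline, np, nc)
  for (i in which(regulated)) {
    cp <- sample(seq_len(nc - 1), 1)
    sgn <- sample(c(-1, 1), 1)
    mu[i, ] <- mu[i, ] + sgn * cfg$effect_size * profile_shape(shapes[i], nc, cp)
  }

  ## per-protein x condition SD matrix
  sdm <- matrix(cfg$noise_sd, np, nc)
  for (i in which(violation == "variance")) {
    sdm[i, sample(nc, 1)] <- cfg$noise_sd * cfg$hetero_factor
  }

  ## support per protein x condition cell
  m <- cfg$peptides_per_condition
  supp <- matrix(m, np, nc)
  n_missing <- integer(np)
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(np * nc) < cfg$missing_rate, np, nc)
    supp[drop] <- sample(0:1, sum(drop), replace = TRUE)
    n_missing <- rowSums(drop)
  }

  total <- sum(supp)
  prot_col <- character(total); cond_col <- character(total)
  rep_col <- character(total); pep_col <- character(total)
  ratio_col <- numeric(total)
  pos <- 0L
  rep_labels <- sprintf("rep%d", seq_len(cfg$replicates))
  for (i in seq_len(np)) {
    heavy <- violation[i] == "normality"
    for (j in seq_len(nc)) {
      nij <- supp[i, j]
      if (nij == 0) next
      eps <- if (heavy) {
        sdm[i, j] * rt(nij, df = 3) / sqrt(3) # unit-variance scaled t(3)
      } else {
        rnorm(nij, 0, sdm[i, j])
      }
      x <- mu[i, j] + eps
      if (contaminant[i]) x <- x * 5^sample(c(-1, 1), nij, replace = TRUE)
      idx <- pos + seq_len(nij)
      prot_col[idx] <- prot[i]
      cond_col[idx] <- conds[j]
      rep_col[idx] <- rep_labels[((seq_len(nij) - 1L) %% cfg$replicates) + 1L]
      pep_col[idx] <- sprintf("%s_pep%02d_%s", prot[i], seq_len(nij), conds[j])
      ratio_col[idx] <- pmax(x, 1e-6)
      pos <- pos + nij
    }
  }
  tab <- peptide_table(protein = prot_col, peptide = pep_col,
                       condition = cond_col, replicate = rep_col,
                       ratio = ratio_col, conditions = conds)
  truth <- data.frame(protein = prot, regulated = regulated, shape = shapes,
                      violation = violation, contaminant = contaminant,
                      n_missing_cells = as.integer(n_missing),
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Simulate a protein profile matrix from Gaussian cluster blobs
#'
#' Rows are drawn as cluster center plus iid Gaussian noise; the returned
#' truth labels enable parameter-recovery tests for every clustering
#' algorithm and validity index.
#'
#' @param n_per_cluster Integer vector, points per cluster.
#' @param centers Numeric matrix, one row per cluster (columns =
#'   conditions), or `NULL` to place `length(n_per_cluster)` centers at
#'   random in `[-1, 1]^n_conditions`.
#' @param n_conditions Number of conditions (columns); required when
#'   `centers` is `NULL`.
#' @param sd Noise standard deviation (> 0, or 0 for the noiseless limit).
#' @param seed Integer seed.
#' @return A list with `matrix` (a `profile_matrix`, see
#'   [aggregate_profiles()]) and `truth` (integer
#'   cluster labels, one per row).
#' @export
#' @examples
#' sim <- simulate_profile_matrix(c(10, 10, 10), sd = 0.1, n_conditions = 4,
#'                                seed = 7)
#' table(sim$truth)
simulate_profile_matrix <- function(n_per_cluster, centers = NULL,
                                    n_conditions = NULL, sd = 0.1, seed = 1) {
  if (length(n_per_cluster) < 1 || any(n_per_cluster < 1)) {
    config_error("need at least one cluster with at least one point")
  }
  if (!is.numeric(sd) || sd < 0) config_error("sd must be >= 0")
  k <- length(n_per_cluster)
  set.seed(seed)
  if (is.null(centers)) {
    if (is.null(n_conditions)) {
      config_error("n_conditions is required when centers is NULL")
    }
    centers <- matrix(runif(k * n_conditions, -1, 1), k, n_conditions)
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != k) {
    config_error("centers must have one row per cluster (%d)", k)
  }
  if (!is.null(n_conditions) && ncol(centers) != n_conditions) {
    config_error("centers have %d columns but n_conditions = %d",
                 ncol(centers), n_conditions)
  }
  p <- ncol(centers)
  n <- sum(n_per_cluster)
  labels <- rep(seq_len(k), n_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(rnorm(n * p, 0, sd), n, p)
  prot <- sprintf("PROT%05d", seq_len(n))
  condn <- sprintf("c%d", seq_len(p))
  dimnames(X) <- list(prot, condn)
  pm <- new_profile_matrix(
    values = X,
    support = matrix(2L, n, p, dimnames = dimnames(X)),
    missing = matrix(FALSE, n, p, dimnames = dimnames(X)),
    imputed = matrix(FALSE, n, p, dimnames = dimnames(X)),
    proteins = prot, conditions = condn, min_support = 2L
  )
  list(matrix = pm, truth = labels)
}
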