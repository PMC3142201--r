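---
title: "Statistical methods behind pepratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind pepratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model, the numerical conventions and
the design decisions of the package. It is a methods reference, not a
tutorial; see the README for a worked example. All code chunks are shown as
source only.

## 1. Data model and assumptions

The unit of observation is a **peptide abundance ratio**: for each peptide
spectrum identified in a stable-isotope labeling experiment (for instance a
15N-labeled reference mixed with a 14N sample), the quantification software
reports the heavy-to-light intensity ratio. A dataset is a long table with
columns `protein`, `peptide`, `condition`, `replicate`, `ratio`, where
`condition` is typically a time point or treatment and several replicates
exist per condition. Ratios must be positive and finite; the package treats
them on the scale supplied (a `log_transform` option is available at read
time for workflows that prefer log-ratios).

The central assumption is that all peptides of one protein measured under the
same condition estimate the same underlying relative abundance, so the
peptide measurements within a protein-condition cell can be pooled. This
gives each protein a one-way layout: groups = conditions, observations =
peptide ratios in all replicates of that condition. The assumption fails for
proteins with differentially modified or mis-assigned peptides; such proteins
tend to surface as assumption-check failures (Section 2) rather than being
silently averaged away.

## 2. Differential regulation testing

For each protein with enough data — at least two conditions with two or more
measurements each, and at least `k + 2` measurements overall for `k`
conditions — four tests are run on its one-way layout:

* **One-way fixed-effects ANOVA.** `F = (SSB / (k - 1)) / (SSW / (N - k))`
  with the usual between/within sums of squares, referred to the
  `F(k - 1, N - k)` distribution. This is the primary test. Two degenerate
  layouts are defined explicitly: zero within-group variance with a
  between-group difference yields `p = 0`, and a constant response yields
  `p = 1`.
* **Kruskal-Wallis.** The rank-based analogue (tie-corrected, chi-square
  with `k - 1` degrees of freedom, via `stats::kruskal.test`), used as the
  distribution-free counterpart.
* **Shapiro-Wilk on pooled residuals.** Residuals from the group means are
  pooled across conditions and tested for normality
  (`stats::shapiro.test`; defined for 3 to 5000 residuals, `NA` outside
  that range).
* **Fligner-Killeen.** A robust test of homogeneity of variances across
  conditions (`stats::fligner.test`).

Each of the four p-value families is corrected across all testable proteins
with the **Holm step-down** procedure (`stats::p.adjust`), which controls
the family-wise error rate without independence assumptions. Holm was chosen
over Benjamini-Hochberg deliberately: in the intended use the significant
list feeds manual follow-up of individual proteins, so family-wise control
is the conservative default.

Each protein is then classified by a fixed precedence:

1. `untestable` — the layout does not meet the minimum data rule;
2. `strict_significant` — ANOVA significant after Holm and *both*
   assumption checks pass;
3. `both_lenient` — ANOVA significant but an assumption is violated, and
   Kruskal-Wallis (which does not need the assumption) confirms;
4. `anova_only_assumptions_violated` — ANOVA significant, assumption
   violated, and Kruskal-Wallis does not confirm: a flag for inspection,
   not a detection;
5. `kw_only` — only the rank test fires (heavy tails can mask a real shift
   from ANOVA);
6. `not_significant`.

The precedence resolves the overlap between categories 3-5 explicitly: a
protein receives the first label whose conditions hold. The
`concordance()` summary reports the Spearman rank correlation between the
raw ANOVA and Kruskal-Wallis p-values across proteins; on realistic mixed
data this correlation is strong (around 0.8), which is the empirical
justification for treating ANOVA as primary and the rank test as a
confirmatory companion rather than running either alone.

## 3. Profile aggregation

Clustering operates on **protein profiles**: one value per protein and
condition, by default the arithmetic mean of all peptide ratios in that cell
(median and trimmed mean are available for contaminated data). A cell with
fewer than `min_support = 2` measurements is flagged missing: a single
spectrum carries no internal replication, and requiring two measurements per
cell filters one-hit identifications, which is standard practice. By default
any protein with a missing cell is dropped; alternatively,
`impute_profiles()` fills up to a per-protein budget of missing cells (one,
by default) with the mean over that protein's observed conditions — a
deliberately neutral value that biases the profile toward "flat" rather
than inventing structure. Proteins above the budget are dropped with a
warning, never silently imputed.

## 4. Clustering algorithms

Four families are provided behind one dispatcher, `cluster_profiles()`:

* **Hierarchical agglomeration** (`single`, `complete`, `average`, `ward`)
  via `stats::hclust`. Ward uses the `ward.D2` convention: it requires
  squared-Euclidean geometry (the package refuses Ward on correlation
  distances), and the reported merge height is `sqrt(2 * delta SS)`, the
  convention under which heights are monotone and comparable to the other
  linkages. The merge-distance curve (height against the number of clusters)
  and its maximum-curvature knee support choosing the cut level.
* **K-means**, a hand-written Lloyd iteration: centers initialized by
  sampling `k` distinct data rows under the supplied seed, assignment by
  minimum squared distance (ties to the lowest index), empty clusters
  reseeded from the datum farthest from its center, and a monotonicity
  assertion on the objective at every step. A single seeded start is run —
  no hidden restarts — so the well-known sensitivity of K-means to
  initialization is *visible* to the reproducibility protocol instead of
  being averaged away. This is a deliberate design choice; users who want a
  consensus answer can run several seeds themselves.
* **Neural gas**, hand-written: all centers move toward every presented
  datum with weights decaying exponentially in the center's distance rank,
  with learning rate and neighborhood range annealed from `0.5` to `0.005`
  and from `k / 2` to `0.01` over 50 epochs. The rank-based soft updates
  make it far less dependent on initialization than K-means.
* **Fuzzy C-means** via `e1071::cmeans` (fuzzifier `m = 2`), with a seeded
  sampled initialization (plus a tiny jitter of `1e-9` to avoid coincident
  prototypes). Memberships are hardened by maximum membership when a
  partition is required.

Distances for the hierarchical methods: Euclidean, `1 - Pearson`
correlation, and `1 - cosine` (uncentered correlation).

## 5. Cluster validation

* **Rand and adjusted Rand index**, hand-written from the contingency pair
  counts. For the degenerate case where the expected index equals the
  maximum index (for example, both partitions trivial), the adjusted index
  is defined as 1 when the partitions are identical and 0 otherwise.
* **Reproducibility protocol**: re-run a stochastic algorithm `reps = 25`
  times at fixed `k` with seeds derived deterministically from one master
  seed, and collect the matrix of pairwise (adjusted) Rand indexes between
  runs. `compare_reproducibility()` summarizes two such matrices with a
  two-sided Mann-Whitney rank-sum test on the off-diagonal values. The
  pairwise values are not independent (every run enters `reps - 1` pairs),
  so this p-value over-states significance; it is reported as a
  descriptive pseudo-replication summary, and the package documentation
  says so explicitly.
* **Figure of Merit**: leave one condition out, cluster on the rest, and
  score the root mean squared deviation of the left-out values from their
  cluster means, summed over left-out conditions and adjusted by
  `sqrt((n - k) / n)` so curves are comparable across `k`. Lower is better;
  the informative feature is where the curve stops dropping.
* **Validity indexes** for selecting the number of clusters:
  Calinski-Harabasz (`(B / (k-1)) / (W / (n-k))`, maximize), Index I
  (`((1/k) (E1/Ek) Dk)^p` with `p = 2`, maximize), Davies-Bouldin (mean
  worst-case `(s_i + s_j) / d_ij` with root-mean-square dispersions,
  minimize), and Krzanowski-Lai
  (`KL(k) = |DIFF(k)| / |DIFF(k+1)|` with
  `DIFF(k) = (k-1)^{2/p} W(k-1) - k^{2/p} W(k)`, maximize). When an index
  sweep starts at `k = 2`, the within-SS at `k = 1` is prepended in closed
  form (the total sum of squares) so the Krzanowski-Lai ratio is defined at
  the lower end of the sweep.
* **Algorithm similarity**: the mean adjusted Rand index between two
  algorithms' partitions across a sweep of `k`, arranged as a symmetric
  matrix — a compact picture of which algorithm families agree on a
  dataset.

## 6. What the synthetic generator emulates

`simulate_peptide_table()` produces data with the failure modes that
motivate the two-track testing strategy, each marked in a ground-truth
table:

* a baseline ratio per protein drawn from `U(0.8, 1.2)` (an unregulated
  protein sits near ratio 1 with calibration wobble);
* Gaussian peptide noise with `noise_sd = 0.25`;
* regulated proteins receive a condition-dependent, mean-centered shift
  pattern (`step`, `ramp` or `pulse`, random sign and changepoint) scaled
  by `effect_size`;
* heteroscedastic proteins have one condition's noise inflated fourfold
  (a Fligner-Killeen target);
* heavy-tailed proteins use scaled Student-t (3 df) noise (a Shapiro-Wilk
  target);
* contaminant proteins have each measurement multiplied or divided by 5
  (keratin-like artifacts);
* a configurable fraction of protein-condition cells is reduced to 0-1
  measurements, which puts them below the default support filter.

Ratios are floored at `1e-6` to respect positivity. The default layout —
five conditions named as a time course (`t0` … `t120`), three replicates,
ten peptides per protein and condition — is the package's own choice of a
representative problem size: large enough that asymptotic behavior (Holm
across hundreds of proteins, rank tests on 50 observations) is realistic,
small enough that the full test suite runs in minutes on one CPU. The
generator emulates the *statistical* structure of labeled proteomics ratio
data, not the instrument pipeline: there is no model of peptide
detectability, intensity-dependent missingness, or isotope-envelope
deconvolution.

`simulate_profile_matrix()` is a simpler fixture generator (Gaussian blobs
around supplied centers) used to test the clustering stack against known
partitions.

## 7. Numerical conventions

* Quartiles and whiskers in `boxplot_summary()` use the type-7 interpolated
  quantile (R's default) and the 1.5 interquartile-range whisker rule.
* All seeds are derived from one master seed via `derive_seed(master, tag)`,
  a string hash reduced modulo a prime below `2^31`; every stage of the
  pipeline and every repetition of a protocol has its own derived seed, so
  results are bit-reproducible end to end and stages can be re-run in
  isolation.
* Tables are written with `%.6g` formatting through a binary-mode
  connection, so writing the same table twice is byte-identical across
  platforms.
* Holm adjustment excludes `NA` p-values from the family size rather than
  failing or treating them as 1.

## 8. Limitations

* The one-way pooling treats peptides within a protein-condition cell as
  exchangeable; shared-peptide proteins and modified peptide forms violate
  this.
* The ANOVA is fixed-effects only; replicate is not modeled as a random
  effect, so systematic replicate offsets inflate the within-group
  variance rather than being absorbed.
* The reproducibility comparison is descriptive (pseudo-replication, see
  Section 5).
* Single-start K-means can land in a poor local optimum on some seeds even
  for clearly separated groups; this is by design (Section 4) but means
  K-means labels should not be consumed without a reproducibility check.
* The generator does not model intensity-dependent missingness, so
  imputation behavior on real data with censored low-abundance peptides is
  not covered by the synthetic benchmarks.
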