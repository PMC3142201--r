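test_that("one-way ANOVA matches the hand sum-of-squares decomposition", {
  res <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  # SSB = 1.5, SSW = 4, F = (1.5/1)/(4/4)
  expect_equal(unname(res["statistic"]), 1.5)
  expect_equal(unname(res["p.value"]), pf(1.5, 1, 4, lower.tail = FALSE))
})

test_that("ANOVA agrees with the linear-model fit and is affine invariant", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(24)
    g <- sample(letters[1:3], 24, replace = TRUE)
    while (min(table(g)) < 2) g <- sample(letters[1:3], 24, replace = TRUE)
    ours <- anova_oneway(x, g)
    ref <- anova(lm(x ~ factor(g)))
    expect_equal(unname(ours["statistic"]), ref$`F value`[1])
    expect_equal(unname(ours["p.value"]), ref$`Pr(>F)`[1])
    shifted <- anova_oneway(3.7 * x + 2, g)
    expect_equal(unname(shifted["statistic"]), unname(ours["statistic"]))
  }
})

test_that("ANOVA edge cases stay finite or NA as documented", {
  # insufficient data -> NA, not an error
  expect_true(is.na(anova_oneway(c(1, 2), c("a", "b"))["p.value"]))
  # zero within-group variance with a between-group difference -> p = 0
  res <- anova_oneway(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(unname(res["p.value"]), 0)
  # constant series -> p = 1
  res <- anova_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(res["p.value"]), 1)
})

test_that("Kruskal-Wallis matches the rank-sum formula and is rank invariant", {
  res <- kruskal_wallis(1:6, rep(c("a", "b"), each = 3))
  # R_a = 6, R_b = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(unname(res["statistic"]), 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  expect_equal(kruskal_wallis(exp(x), g)["statistic"],
               kruskal_wallis(x, g)["statistic"])
  expect_equal(unname(kruskal_wallis(rep(2, 8),
                                     rep(c("a", "b"), each = 4))["p.value"]),
               1)
})

test_that("Shapiro-Wilk runs on pooled residuals with affine invariance", {
  set.seed(8)
  x <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  p1 <- shapiro_wilk_residuals(x, g)
  p2 <- shapiro_wilk_residuals(2.5 * x + 1, g)
  expect_equal(p1, p2)
  expect_equal(p1, shapiro.test(x - ave(x, g))$p.value)
  expect_true(is.na(shapiro_wilk_residuals(c(1, 2), c("a", "b"))))
})

test_that("Fligner-Killeen detects scale differences and not symmetric spread", {
  # identical deviation patterns around the group medians -> statistic 0
  p <- fligner_killeen(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(p, 1)
  # two points per group: the normalized scores have zero variance, which is
  # undefined for the test and maps to NA
  expect_true(is.na(fligner_killeen(c(1, 3, 2, 4), c("a", "a", "b", "b"))))
  set.seed(12)
  x <- c(rnorm(200), 100 * rnorm(200))
  g <- rep(c("a", "b"), each = 200)
  expect_lt(fligner_killeen(x, g), 0.05)
  expect_true(is.na(fligner_killeen(c(1, 2), c("a", "b"))))
})

test_that("Holm adjustment follows the step-down rule and handles NA", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # NA stays NA and is excluded from the family size
  expect_equal(holm_adjust(c(0.01, NA, 0.04, 0.03)),
               c(0.03, NA, 0.06, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (rep in 1:10) {
    p <- runif(sample(3:20, 1))
    adj <- holm_adjust(p)
    # order invariance
    ord <- sample(length(p))
    expect_equal(adj[ord], holm_adjust(p[ord]))
    # dominated by Bonferroni
    expect_true(all(adj <= pmin(length(p) * p, 1) + 1e-12))
    # adjusted >= raw
    expect_true(all(adj >= p))
  }
})

test_that("run_differential classifies proteins per the decision rule", {
  sim <- simulate_peptide_table(simulation_config(
    n_proteins = 60, frac_regulated = 0.25, effect_size = 1.5,
    frac_heteroscedastic = 0.1, frac_heavy_tailed = 0.1, seed = 19
  ))
  res <- run_differential(sim$table, alpha = 0.05)
  expect_setequal(res$protein, sim$truth$protein)
  # adjusted >= raw in every family
  for (col in c("anova_p", "kw_p", "shapiro_p", "fligner_p")) {
    adj <- res[[paste0(col, "_adj")]]
    ok <- !is.na(adj) & !is.na(res[[col]])
    expect_true(all(adj[ok] >= res[[col]][ok]))
  }
  # classification is consistent with the adjusted p-values
  a <- res$anova_p_adj < 0.05
  k <- res$kw_p_adj < 0.05
  viol <- (res$shapiro_p_adj < 0.05) | (res$fligner_p_adj < 0.05)
  strict <- res$classification == "strict_significant"
  expect_true(all(a[strict] & !viol[strict]))
  kwonly <- res$classification == "kw_only"
  expect_true(all(k[kwonly] & !a[kwonly]))
})

test_that("a single-protein table gets adjusted = raw in every family", {
  sim <- simulate_peptide_table(simulation_config(n_proteins = 1, seed = 2))
  res <- run_differential(sim$table)
  expect_equal(res$anova_p_adj, res$anova_p)
  expect_equal(res$kw_p_adj, res$kw_p)
  expect_equal(res$shapiro_p_adj, res$shapiro_p)
  expect_equal(res$fligner_p_adj, res$fligner_p)
})

test_that("strongly regulated Gaussian proteins are recovered strictly", {
  sim <- simulate_peptide_table(simulation_config(
    n_proteins = 100, frac_regulated = 0.2, effect_size = 1, seed = 23
  ))
  res <- run_differential(sim$table, alpha = 0.05)
  reg <- sim$truth$regulated[match(res$protein, sim$truth$protein)]
  recovered <- res$classification[reg] == "strict_significant"
  expect_gte(mean(recovered), 0.9)
  # family-wise control on the unregulated set
  expect_equal(sum(res$anova_p_adj[!reg] < 0.05, na.rm = TRUE), 0)
})

test_that("Spearman concordance matches a rank-then-Pearson oracle", {
  sim <- simulate_peptide_table(simulation_config(
    n_proteins = 40, frac_regulated = 0.3, seed = 29
  ))
  res <- run_differential(sim$table)
  conc <- concordance(res)
  oracle <- cor(rank(res$anova_p), rank(res$kw_p))
  expect_equal(conc$spearman_rho, oracle, tolerance = 1e-12)
  expect_gt(conc$spearman_rho, 0.5) # the strong-correlation regime
  expect_lte(conc$n_overlap_lenient, min(conc$n_anova_sig, conc$n_kw_sig))

  # perfect and inverted agreement
  fake <- res
  fake$kw_p <- fake$anova_p
  expect_equal(concordance(fake)$spearman_rho, 1)
  fake$kw_p <- 1 - fake$anova_p
  expect_equal(concordance(fake)$spearman_rho, -1)
})

test_that("box-whisker summaries follow the interpolated-quartile convention", {
  bs <- boxplot_summary(c(1, 2, 3, 4, 5), rep("a", 5))
  expect_equal(bs$median, 3)
  expect_equal(bs$q1, 2)
  expect_equal(bs$q3, 4)
  expect_equal(bs$n_outliers, 0)

  one <- boxplot_summary(7, "a")
  expect_equal(unlist(one[c("whisker_low", "q1", "median", "q3",
                            "whisker_high")], use.names = FALSE),
               rep(7, 5))

  out <- boxplot_summary(c(1, 2, 3, 4, 5, 100), rep("a", 6))
  expect_equal(attr(out, "outliers")$a, 100)
  expect_true(with(out, whisker_low <= q1 & q1 <= median &
                     median <= q3 & q3 <= whisker_high))

  two <- boxplot_summary(c(1, 2, 3, 10, 11, 12),
                         rep(c("a", "b"), each = 3))
  expect_equal(two$group, c("a", "b"))
  expect_equal(two$median, c(2, 11))
})
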