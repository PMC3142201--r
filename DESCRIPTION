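Package: pepratio
Type: Package
Title: Differential Regulation Testing and Cluster Validation for
    Isotope-Labeled Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of stable-isotope (15N/14N) peptide abundance-ratio
    tables from quantitative proteomics time-course and condition-contrast
    experiments. Answers two questions: which proteins are differentially
    regulated (peptide-level one-way ANOVA and Kruskal-Wallis tests with
    Shapiro-Wilk and Fligner-Killeen assumption checks and Holm family-wise
    error correction), and which proteins are co-regulated (protein-profile
    aggregation followed by hierarchical, partitioning and fuzzy clustering,
    validated by Rand-index reproducibility protocols, Figure of Merit, and
    the Calinski-Harabasz, Index I, Davies-Bouldin and Krzanowski-Lai
    cluster-validity indexes). Includes a synthetic-data generator emulating
    replicated multi-condition ratio data with ground truth, and an
    end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
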