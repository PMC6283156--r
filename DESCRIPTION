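Package: riailqtl
Title: QTL Linkage Mapping, Heritability, and Hotspot Analysis for
    Recombinant Inbred Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for two-parent recombinant
    inbred advanced intercross line (RIAIL) panels phenotyped with a
    large-particle sorter. Implements per-well summarization of sorter
    records into 24 growth-response traits with assay-effect and
    control-condition regression; principal-component trait reduction
    with a 90 percent cumulative-variance rule and correlation-based
    trait clustering; single-marker LOD scans with forward cofactor
    search, permutation genome-wide significance thresholds, 1.5-LOD-drop
    confidence intervals, and a two-dimensional marker-pair interaction
    scan; broad-sense heritability and restricted maximum likelihood
    variance components with an additive genotype-correlation kernel and
    a Hadamard-product pairwise-interaction kernel; empirical genetic-map
    estimation with equal-centimorgan binning and Poisson-threshold QTL
    hotspot detection; and the near-isogenic line and chromosome
    substitution strain phenotype-categorization decision trees. A
    synthetic-data generator with known additive and epistatic
    architecture makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
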