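Package: classrank
Title: Susceptibility of Gene Classes to Expression Perturbation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether a designated class of genes (for example,
    imprinted genes) is more susceptible to, or protected from,
    transcriptome-wide expression perturbation than the genome at large.
    Provides per-gene differential expression with Benjamini-Hochberg
    false discovery rate control, FDR-rank distribution profiles compared
    against random and control gene classes, a ROC/AUC gene-label
    permutation test, running-sum gene set enrichment with
    permutation-based normalisation, two-way ANOVA variance partitioning
    for candidate genes measured in factorial crosses, and a synthetic
    transcriptome generator with planted ground truth for calibration and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
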