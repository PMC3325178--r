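#!/usr/bin/env Rscript
# Stage 1: simulate the study.
#
# Emulates a two-condition foetal-tissue transcriptome study of maternal
# undernutrition: 10,000 genes across control (C) and undernourished (UN)
# conditions, n = 10 per condition nested in litters, with three planted
# gene classes — 200 responsive genes shifted +/- 1.5-fold, 500
# housekeeping genes at half the residual noise, and a 90-gene neutral
# class standing in for the imprinted genes whose behaviour the analysis
# interrogates. Writes the matrix, sample annotation, gene sets (GMT) and
# the ground-truth ledger under results/data/.

suppressPackageStartupMessages(library(classrank))

seed <- 101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- synthetic_design(seed = seed)
print(design)

study <- generate_expression(design)
write_expression_tsv(study$expr,
                     file.path(out, "expression.tsv"),
                     file.path(out, "samples.tsv"))
utils::write.table(study$truth, file.path(out, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

sets <- generate_gene_sets(study$truth, n_random = 3,
                           seed = derive_seed(seed, 1L))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
print(sets)

cat(sprintf("wrote %d-gene x %d-sample study to %s\n",
            nrow(study$expr$values), ncol(study$expr$values), out))
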