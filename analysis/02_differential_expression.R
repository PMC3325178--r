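#!/usr/bin/env Rscript
# Stage 2: per-gene differential expression, UN vs C.
#
# Filters unexpressed genes, runs the unpaired two-sample t-test per gene,
# applies Benjamini-Hochberg FDR control, ranks the transcriptome by
# q-value, and reports the significant-gene counts plus the estimated
# power to resolve a 1.5-fold change. Also runs the sex-stratified
# contrasts. Writes results/de.tsv and results/de_by_sex/*.tsv.

suppressPackageStartupMessages(library(classrank))

expr <- read_expression_tsv("results/data/expression.tsv",
                            "results/data/samples.tsv")
expr <- filter_unexpressed(expr, floor = 0)

de <- de_test(expr, reference = "C", contrast = "UN")
write_de_tsv(de, "results/de.tsv")

calls <- call_significant(de, q_cut = 0.05)
cat(sprintf("%d genes significant at q < 0.05: %d up-regulated, %d down-regulated\n",
            length(calls$up) + length(calls$down),
            length(calls$up), length(calls$down)))

pw <- power_fold_change(1.5, alpha = 0.05, n_per_group = 10, sd = 0.2)
cat(sprintf("power to resolve a 1.5-fold change: %.0f%%\n", 100 * pw$power))

dir.create("results/de_by_sex", showWarnings = FALSE)
for (sex in c("F", "M")) {
  de_s <- de_test(expr, "C", "UN", stratify = list(sex = sex))
  write_de_tsv(de_s, file.path("results/de_by_sex", paste0(sex, ".tsv")))
  cs <- call_significant(de_s, 0.05)
  cat(sprintf("  %s only (n = %d/group): %d significant\n", sex,
              sum(expr$samples$sex == sex) / 2,
              length(cs$up) + length(cs$down)))
}
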