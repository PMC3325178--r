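#!/usr/bin/env Rscript
# Stage 6: candidate genes in the 2x2 factorial cross.
#
# Emulates the qPCR panel of the second-generation crosses (CC/CU/UC/UU,
# first letter the dam): twelve candidate genes at n = 6 per cell, one of
# which carries a planted maternal-nutrition component of variance. A
# two-way ANOVA partitions each gene's expression variance into maternal,
# paternal and interaction percent contributions, and the one-way
# ANOVA/Bonferroni post-tests compare each exposed cross with CC.

suppressPackageStartupMessages(library(classrank))

seed <- 101L
dir.create("results", showWarnings = FALSE)

# eleven null candidates plus one with an 8% maternal variance component
null_cand <- generate_factorial_candidates(
  c(maternal = 0, paternal = 0, interaction = 0),
  n_per_cell = 6, genes = paste0("cand", 1:11),
  seed = derive_seed(seed, 5L))
hit_cand <- generate_factorial_candidates(
  c(maternal = 0.08, paternal = 0, interaction = 0),
  n_per_cell = 6, genes = "cand12", seed = derive_seed(seed, 6L))
cand <- rbind(null_cand, hit_cand)

part <- two_way_anova(cand)
write_anova_tsv(part, "results/anova.tsv")
cat("percent of expression variance attributable to each factor:\n")
print(part[, c("gene_id", "pct_maternal", "pct_paternal",
               "pct_interaction", "p_maternal", "p_paternal",
               "p_interaction")], digits = 2)

cat("\none-way ANOVA with Bonferroni post-tests vs CC, per gene:\n")
for (g in unique(cand$gene)) {
  sub <- cand[cand$gene == g, ]
  res <- one_way_bonferroni(sub, comparisons = list(c("CC", "CU"),
                                                    c("CC", "UC"),
                                                    c("CC", "UU")))
  hits <- res$posthoc[res$posthoc$adjusted_p < 0.05, ]
  cat(sprintf("  %-7s omnibus p = %.3f%s\n", g, res$omnibus$p,
              if (nrow(hits)) paste0("; ",
                paste(sprintf("%s vs %s adj p = %.3f", hits$group1,
                              hits$group2, hits$adjusted_p),
                      collapse = ", ")) else ""))
}
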