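#!/usr/bin/env Rscript
# Stage 5: gene set enrichment analysis.
#
# Running-sum enrichment of every gene class along the signed-t ordering
# (unweighted walk, 1000 gene-set permutations), with normalised
# enrichment scores and tail-ratio FDR q-values. A neutral class is
# expected to come out with |NES| near 1 and a large q-value; the
# responsive control (which is perturbed in both directions) reaches a
# large |NES|.

suppressPackageStartupMessages(library(classrank))

seed <- 101L
de <- utils::read.delim("results/de.tsv", stringsAsFactors = FALSE)
sets <- gene_set_collection(read_gmt("results/data/gene_sets.gmt"),
                            de$gene_id)

tab <- gsea(stats::setNames(de$statistic, de$gene_id), sets,
            n_perm = 1000, exponent = 0, seed = derive_seed(seed, 4L),
            pos_label = "UN", neg_label = "C")
write_gsea_tsv(tab, "results/gsea.tsv")
print(as.data.frame(tab)[, c("set", "size", "direction", "nes", "fdr_q")],
      digits = 3)
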