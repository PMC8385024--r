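#!/usr/bin/env Rscript
# Annotation enrichment of the down-regulated secretome against the
# quantifiable background, and two-group permutation GSEA between the
# anchor-high and anchor-low tissue halves.

library(protlayers)

seed <- as.integer(Sys.getenv("PROTLAYERS_SEED", "7"))
sets <- read_gmt("results/layers/sets.gmt")
st <- read.delim("results/secretome_stats.tsv")
quant <- st[st$quantifiable, ]

fish <- fisher_annotation_enrichment(quant$gene[quant$dep_flag == "down"],
                                     quant$gene, sets, fdr = 0.02)
write.table(fish, "results/annotation_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("annotation enrichment: top set %s (EF %.2f, q = %.2g)\n",
            fish$set[1], fish$ef[1], fish$q[1]))

ann <- read.delim("results/layers/tissue_samples.tsv")
tissue <- read_quant_matrix("results/layers/tissue.tsv", layer = "tissue",
                            scale = "log2",
                            stage = setNames(ann$stage, ann$sample))
split <- split_by_median(tissue, "MMP2")
groups <- setNames(ifelse(colnames(tissue$values) %in% split$high,
                          "high", "low"), colnames(tissue$values))
cat(sprintf("anchor split: %d high / %d low\n",
            length(split$high), length(split$low)))

gsea <- gsea_permutation(tissue, groups, sets, n_perm = 1000, seed = seed,
                         fdr = 0.25)
write.table(gsea[setdiff(names(gsea), "leading_edge")], "results/gsea.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
hits <- gsea[gsea$significant, ]
cat(sprintf("GSEA: %d/%d sets at FDR < 0.25; best: %s (NES %.2f, q = %.2g)\n",
            nrow(hits), nrow(gsea), gsea$set[which.max(gsea$nes)],
            max(gsea$nes, na.rm = TRUE), min(gsea$q_fdr, na.rm = TRUE)))
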