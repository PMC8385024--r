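#!/usr/bin/env Rscript
# Transcription-factor regulon activity (ssGSEA, exponent 0.25) correlated
# with the anchor protein, a tissue-wide Spearman screen, and KSEA kinase
# z-scores on the phosphosite fold changes.

library(protlayers)

ann <- read.delim("results/layers/tissue_samples.tsv")
tissue <- read_quant_matrix("results/layers/tissue.tsv", layer = "tissue",
                            scale = "log2",
                            stage = setNames(ann$stage, ann$sample))
anchor <- split_by_median(tissue, "MMP2")$values

expr <- read_quant_matrix("results/layers/transcriptome.tsv",
                          layer = "transcriptome", scale = "log2")
regulons <- read_regulons("results/layers/tf_targets.tsv")
act <- regulon_activity(expr, regulons, alpha = 0.25, anchor_vector = anchor)
write.table(act$correlation, "results/tf_activity_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(tf = rownames(act$scores), act$scores),
            "results/tf_activity_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("TF activity vs anchor (Spearman):\n")
print(act$correlation, digits = 3)

scr <- spearman_screen(tissue, anchor)
cat(sprintf("tissue proteins positively correlated with the anchor (p<0.05): %d/%d\n",
            scr$n_positive_significant, nrow(scr$table)))

phospho <- read.delim("results/layers/phospho.tsv")
ksmap <- read.delim("results/layers/kinase_substrates.tsv")
kinase_map <- split(ksmap$site_id, ksmap$kinase)
ks <- ksea(phospho, kinase_map, min_substrates = 5)
write.table(ks, "results/ksea.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("KSEA (anchor-high vs anchor-low):\n")
print(head(ks, 5), digits = 3)
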