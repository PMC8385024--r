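#!/usr/bin/env Rscript
# Fisher association of plasma/tissue trend clusters with the secretome
# fold-change categories (enrichment factors, BH FDR 0.02), and the
# three-way signature intersection.

library(protlayers)

st <- read.delim("results/secretome_stats.tsv")
cat_by_gene <- setNames(st$category, st$gene)
cat_by_gene <- cat_by_gene[!is.na(cat_by_gene)]

assoc <- function(tag) {
  cl <- read.delim(sprintf("results/%s_clusters.tsv", tag))
  cl_by_gene <- setNames(cl$cluster, cl$gene)
  am <- association_matrix(cl_by_gene, cat_by_gene, fdr = 0.02)
  write.table(am, sprintf("results/%s_association.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  top <- am[which.max(ifelse(is.na(am$ef), -Inf, am$ef)), ]
  cat(sprintf("%s: top pair cluster %s x category %s, EF %.2f (q = %.2g)\n",
              tag, top$cluster, top$category, top$ef, top$q))
  list(am = am, top = top, cl_by_gene = cl_by_gene)
}

pl <- assoc("plasma")
ti <- assoc("tissue")

sig <- intersect_signature(list(
  secretome_cat1 = names(cat_by_gene)[cat_by_gene == pl$top$category],
  plasma_cluster = names(pl$cl_by_gene)[pl$cl_by_gene == pl$top$cluster],
  tissue_cluster = names(ti$cl_by_gene)[ti$cl_by_gene == ti$top$cluster]))
write.table(data.frame(gene = sig$signature), "results/signature.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sig$regions, "results/venn_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("three-way signature: %d proteins (MMP2 included: %s)\n",
            length(sig$signature), "MMP2" %in% sig$signature))
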