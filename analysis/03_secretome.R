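#!/usr/bin/env Rscript
# Orient the forward/reverse SILAC ratios to log2(KD/control), aggregate
# replicates, call differentially secreted proteins (1.5-fold, p < 0.05)
# and assign the three fold-change categories.

library(protlayers)

sil <- read_silac("results/layers/silac.tsv")
st <- aggregate_replicates(orient_ratios(sil), min_obs = 3)
st <- call_deps(st, fc_threshold = 1.5, alpha = 0.05)
st <- categorize(st)

write.table(st, "results/secretome_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
volcano <- data.frame(gene = st$gene, mean_log2fc = st$mean,
                      neg_log10_p = -log10(st$p))
write.table(volcano[st$quantifiable, ], "results/secretome_volcano.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d proteins, %d quantifiable (>=3 of %d replicates)\n",
            nrow(st), sum(st$quantifiable), ncol(sil$ratios)))
cat(sprintf("differentially secreted: %d down, %d up\n",
            sum(st$dep_flag == "down"), sum(st$dep_flag == "up")))
print(table(category = st$category))
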