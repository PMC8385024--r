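#!/usr/bin/env Rscript
# Generate all five synthetic data layers (pooled 4-stage plasma profiles,
# forward/reverse SILAC secretome, 95-patient tissue cohort, matched
# transcriptome, phosphosite fold changes) with known ground truth.
# Downstream scripts read the written layer files only.

library(protlayers)

seed <- as.integer(Sys.getenv("PROTLAYERS_SEED", "7"))
outdir <- "results/layers"

cfg <- generator_config(seed = seed)
sim <- simulate_layers(cfg)
paths <- write_layers(sim, outdir)

cat(sprintf("seed %d -> %s\n", seed, outdir))
cat(sprintf("plasma: %d proteins x 4 stages (%.1f%% missing)\n",
            nrow(sim$plasma$values), 100 * mean(is.na(sim$plasma$values))))
cat(sprintf("secretome: %d proteins x %d SILAC replicates (%d planted at log2 %.2f)\n",
            nrow(sim$silac$ratios), ncol(sim$silac$ratios),
            length(sim$truth$planted_module), cfg$planted_effect))
cat(sprintf("tissue: %d proteins x %d patients; transcriptome: %d genes; phospho: %d sites\n",
            nrow(sim$tissue$values), ncol(sim$tissue$values),
            nrow(sim$transcriptome$values), nrow(sim$phospho)))
cat("files:", paste(basename(paths), collapse = " "), "\n")
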