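---
title: "Multi-layer proteome integration: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer proteome integration: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlayers)
```

## The problem

A protein that drives tumour invasion should leave a coherent trace across
several measurement layers at once: its secretion from cancer cells should
respond to perturbing the driver, its abundance in patient plasma and tumour
tissue should track clinical stage, and its downstream signalling should be
visible in the transcriptome and phosphoproteome of the same patients.
`protlayers` implements that integrative argument for the matrix
metalloproteinase MMP-2 in colorectal cancer: knock the protease down in a
cell line, quantify what its secretome loses, and ask whether exactly those
proteins rise in patient plasma and tissue as disease progresses from TNM
stage I to II — then corroborate the mechanism (focal-adhesion-kinase
signalling) with gene-set, transcription-factor and kinase activity scores.

Because the pipeline's value is the chain of inferences rather than any one
statistic, every stage is a small, separately testable operation, and a
synthetic-data generator produces all five layers with known ground truth so
each stage has a recovery test that needs no external download.

## Stage models

### Stage-profile clustering

Per-protein abundances are averaged within TNM stage (tissue cohorts first
collapse 95 patients to 4 stage means), z-scored per row
($z = (x - \bar x)/s$, sample sd by default), and clustered by
agglomerative hierarchical clustering on Euclidean distance. Clusters are
the connected components of merges *strictly below* a distance threshold.
The conventional published threshold for this kind of tree is 1.578; for
simulated trees the package instead calibrates the cut with
`threshold_for_k()` (the midpoint of the merge-height gap that yields the
target cluster count), because an absolute height is only meaningful for
the tree it was chosen on. Rows are sorted by analyte key before
clustering, which makes the merge sequence — and therefore the labels —
invariant to input row order; labels are renumbered by decreasing cluster
size with ties broken by smallest member key.

Rows with a missing stage or zero variance are excluded and reported, not
imputed or zero-filled: imputation would manufacture trend shapes, which
are exactly what the clustering measures. Users who prefer imputation can
do it upstream and feed the completed matrix back in.

### SILAC secretome

Replicates alternate label orientation: *forward* runs culture the
knockdown line in heavy medium, so $\log_2(H/L) = \log_2(KD/control)$;
*reverse* runs swap the labels and flip the sign. `orient_ratios()` folds
both onto the knockdown/control scale; everything downstream sees oriented
ratios only, which makes the whole analysis exactly invariant to negating
the raw ratios while swapping every orientation flag (a property the tests
assert bit-for-bit).

Proteins quantified in at least 3 of 6 replicates are tested with a
two-sided one-sample t-test of the mean oriented log ratio against 0 and
BH-adjusted. The t-test is the field standard at $n = 3\ldots6$; variance
moderation was deliberately left out to keep the per-protein statistic
self-contained (a moderated test would change no category, since categories
use the fold change alone). Zero-variance proteins get
`p = .Machine$double.xmin` with a warning rather than an error, because a
protein seen identically three times is evidence, not a defect.

Two thresholds act separately, matching how such data are reported:
differential secretion requires both $|\bar x| \ge \log_2 1.5$ and
p < 0.05 (`use_adjusted` switches to the BH q); the three *categories*
(1: down, 2: unchanged, 3: up) use the fold change only, with the boundary
value $\pm\log_2 1.5$ assigned to the extreme category. That is why a
category-1 protein can carry p = 0.122. The replicate mean, not the
median, summarises the six ratios; a median would be less efficient at
n = 6 under approximately Gaussian log-ratio noise.

### Cross-layer association

Layers are joined on gene symbol (accession as fallback) — the only key
stable across search engines and data sources; within-matrix collisions
keep the row with the highest mean abundance. Over the common universe of
size $N$, each (cluster, category) cell with overlap $k$, cluster size $K$
and category size $n$ gets an enrichment factor
$EF = kN/(Kn)$ (observed over expected) and a one-sided hypergeometric
p-value; BH adjustment spans all cells of one panel, because the published
use of such panels states a single FDR for the whole matrix. One-sided
*greater* is the default since enrichment is the reported signal;
`two_sided` is selectable. $EF$ is reported as 0 (not NA) when $k = 0$ so
depleted cells stay visible.

The final signature is the three-way intersection of the down-regulated
secretome category with the most-enriched plasma and tissue clusters, with
all Venn region counts reported.

### Gene-set and activity scores

*Fisher annotation enrichment* reuses the same 2×2 machinery against an
explicit background (never an implicit genome).

*Two-group GSEA* ranks genes by signal-to-noise
$(\bar x_A - \bar x_B)/(s_A + s_B)$ with each sd floored at
$\max(0.2\,|\bar x|,\ 0.2)$, the conventional two-class metric; a plain
log-fold-change metric is selectable. The enrichment score is the weighted
Kolmogorov–Smirnov running sum (weight exponent 1 by default; 0 recovers
the classic unweighted statistic). Significance comes from phenotype-label
permutations — valid at the 47/48 split this pipeline targets — with NES
normalisation by same-sign permutation means and the standard pooled-NES
FDR; below 3 samples per group the test falls back to gene-set permutation
with a warning.

*ssGSEA regulon activity* scores each transcription factor per sample as
the rank-weighted cumulative ECDF difference between its targets and all
other genes, exponent 0.25 and no cross-sample renormalisation. Being
rank-based, the score is invariant to any strictly increasing transform of
a sample's expression (tested), so the log2(x+1) input convention is a
convenience, not a requirement. Regulons exclude computationally predicted
edges on input.

*KSEA* uses the canonical mean-substrate z-score
$z = (\bar x_{sub} - \bar x_{all})\sqrt{m}/s_{all}$ with a two-sided
normal p and BH q, requiring 5 substrates per kinase and 50 sites overall
for a stable background.

*Median split*: samples are sorted by decreasing anchor abundance with
label tie-break; the top $\lfloor n/2 \rfloor$ are "high", so 95 patients
split 47/48 — the median sample goes to the low group.

## The synthetic generator

`generator_config()` defaults are the study conditions the pipeline is
tested under, chosen once:

* plasma: 1000 proteins, 11 trend archetypes, per-entry noise sd 0.3
  (z-units), 5% missingness completely at random;
* secretome: 800 proteins, 6 replicates (3 forward + 3 reverse), 10%
  planted at a true effect of −1.0 log2 units (comfortably past the
  −log2 1.5 ≈ −0.585 category boundary), replicate noise sd 0.25, 10%
  dropout;
* tissue: 1200 proteins, 95 patients (stage mix 25/30/30/15%), 16
  archetypes, patient-level shift sd 0.2;
* transcriptome: 2000 genes, five factors (ETS1, JUN, KLF8, NFKB1, YBX1)
  with 25 targets each, latent activity correlated 0.8 with the anchor;
* phosphoproteome: 1000 sites, 10 kinases × 25 substrates, one active
  kinase shifted by 0.8 with site noise sd 0.5 — giving an expected KSEA
  z of $0.8\sqrt{25}/0.5 = 8$.

523 genes are planted as common to plasma and secretome (and carried in
tissue), with an 80-gene co-secretion module — plus the knockdown target
itself — concentrated in the sharp stage-I→II-riser cluster of both
cohort layers. Archetypes are spread near-uniformly over the sphere of
valid z-profiles by a Fibonacci lattice, then rotated so archetype 1 is
the I→II riser: this guarantees mutual separation without hand-tuning 16
shapes. A single root seed expands into fixed per-layer child seeds
(`(seed + 104729·k) mod (2^31 − 1)`) so layers can be regenerated
independently and structure sizes never depend on the seed.

What the generator deliberately does **not** model: per-patient plasma
variation (the emulated design pools plasma by stage), informative
missingness (dropout is completely at random, whereas real LFQ missingness
is abundance-dependent), peptide-level quantitation, batch effects, and
correlated noise between proteins of a cluster. Recovery tests passing on
this generator therefore show the *logic* of each stage is right — they do
not certify performance on real cohort data with structured missingness.

## Numerical choices and degenerate inputs

* Cuts are strict (`height < threshold`); boundary-height merges start new
  clusters.
* Fold-change category boundaries are inclusive toward the extreme
  category.
* BH is `stats::p.adjust`; tests verify it against a direct sort/cummin
  oracle.
* Fisher p-values use `stats::phyper` (one-sided) or `stats::fisher.test`
  (two-sided); tests verify against exhaustive enumeration for all
  universes up to 60.
* All-zero hit weights in a GSEA set fall back to equal weights; a set
  with no genes in the ranked list is NA, never 0.
* A constant anchor still splits (label order) but warns; an anchor seen
  in fewer than 4 samples errors.
* Spearman p uses the t approximation on ranked Pearson with average
  ranks; fewer than 5 paired observations gives NA.

## Problem sizes in the test-suite

The tests run the full default generator (1000/800/1200 proteins, 95
patients) for the recovery checks, 500-permutation GSEA on a
1000-gene × 40-sample matrix for the null calibration, and smaller
configurations (≈150 proteins, 24 patients, 100 permutations) for the
end-to-end pipeline and property tests. These sizes were chosen so the
whole suite completes in well under five minutes while keeping every
statistical check at the scale its approximations assume.

## Known limitations

* The clustering threshold/k correspondence is tree-specific; comparing
  cluster counts across datasets at a fixed height is not meaningful.
* The pooled-plasma design means plasma cluster membership carries no
  patient-level uncertainty; treat plasma clusters as descriptive.
* Phenotype-permutation GSEA needs tens of samples per group for stable
  FDR; the gene-set fallback changes the null hypothesis (gene
  exchangeability rather than phenotype exchangeability) and its p-values
  are not directly comparable.
* KSEA treats substrate sites as independent; shared peptides or
  multi-kinase sites violate that and inflate |z| modestly.
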