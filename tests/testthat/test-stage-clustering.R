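mk_stage_qm <- function(values, genes = NULL, stage = NULL) {
  quant_matrix(values, gene_symbol = genes, layer = "plasma", scale = "log2",
               stage = stage)
}

test_that("collapse_to_stage_means averages within stage and drops gaps", {
  v <- matrix(c(1, 3, 2, 4, 5, 7, 6, 8,
                1, NA, NA, 4, 5, 7, 6, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), paste0("s", 1:8)))
  stage <- setNames(rep(c("I", "II", "III", "IV"), each = 2), paste0("s", 1:8))
  out <- collapse_to_stage_means(mk_stage_qm(v, stage = stage))
  expect_equal(unname(out$values["P1", ]), c(2, 3, 6, 7))
  expect_equal(unname(out$values["P2", "I"]), 1)   # single observation kept

  # a protein with a fully unobserved stage is dropped
  v2 <- v; v2["P2", c("s3", "s4")] <- NA
  expect_message(out2 <- collapse_to_stage_means(mk_stage_qm(v2, stage = stage)),
                 "dropped 1")
  expect_equal(rownames(out2$values), "P1")
})

test_that("collapse is the identity on an already-4-column stage matrix", {
  v <- matrix(rnorm(8), 2, 4, dimnames = list(c("P1", "P2"), c("I", "II", "III", "IV")))
  qm <- mk_stage_qm(v, stage = setNames(colnames(v), colnames(v)))
  expect_identical(collapse_to_stage_means(qm)$values, v)
})

test_that("z-scoring matches hand-computed values and handles degenerate rows", {
  v <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                1, NA, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("I", "II", "III", "IV")))
  prof <- zscore_profiles(mk_stage_qm(v), ddof = 1)
  expect_equal(unname(prof$z["P1", ]),
               c(-1.161895, -0.387298, 0.387298, 1.161895), tolerance = 1e-6)
  expect_setequal(prof$dropped$accession, c("P2", "P3"))
  expect_equal(prof$dropped$reason[prof$dropped$accession == "P2"], "constant")
  expect_equal(prof$dropped$reason[prof$dropped$accession == "P3"], "incomplete")

  # population sd divisor
  prof0 <- zscore_profiles(mk_stage_qm(v), ddof = 0)
  expect_equal(unname(prof0$z["P1", ]),
               (c(1, 2, 3, 4) - 2.5) / (sd(1:4) * sqrt(3 / 4)), tolerance = 1e-9)
})

test_that("z-scores are invariant to positive affine transforms per row", {
  set.seed(1)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("P%02d", 1:10), c("I", "II", "III", "IV")))
  za <- zscore_profiles(mk_stage_qm(v))$z
  zb <- zscore_profiles(mk_stage_qm(v * 2.7 + 13))$z
  expect_equal(za, zb, tolerance = 1e-9)
})

test_that("mean-zero and unit-sd invariants hold on generated profiles", {
  cfg <- tiny_config()
  prof <- zscore_profiles(generate_stage_profiles(cfg))
  expect_equal(rowMeans(prof$z), rep(0, nrow(prof$z)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(prof$z, 1, sd), rep(1, nrow(prof$z)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("nearest pairs merge first and identical profiles merge at height 0", {
  v <- matrix(c(0, 0, 0, 0.01,
                0, 0, 0, 0.01,
                5, 5, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("I", "II", "III", "IV")))
  prof <- structure(list(z = v, gene_symbol = rep("", 3),
                         dropped = data.frame(), ddof = 1, layer = "plasma"),
                    class = "stage_profiles")
  dend <- hierarchical_cluster(prof)
  expect_equal(min(dend$tree$height), 0)
  expect_equal(sort(dend$tree$merge[1, ]), c(-2, -1))  # A and B first

  # 3 colinear points: the closest pair merges first
  v2 <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("A", "B", "C"), "x"))
  prof2 <- structure(list(z = v2, gene_symbol = rep("", 3),
                          dropped = data.frame(), ddof = 1, layer = "plasma"),
                     class = "stage_profiles")
  d2 <- hierarchical_cluster(prof2)
  expect_equal(sort(d2$tree$merge[1, ]), c(-2, -1))
  expect_equal(d2$tree$height[1], 1)
})

test_that("merge heights and threshold cuts match a brute-force agglomerator", {
  set.seed(9)
  z <- rbind(matrix(rnorm(40, 0, 0.3), 10, 4), matrix(rnorm(40, 3, 0.3), 10, 4))
  rownames(z) <- sprintf("P%02d", 1:20); colnames(z) <- c("I", "II", "III", "IV")
  prof <- structure(list(z = z, gene_symbol = rep("", 20),
                         dropped = data.frame(), ddof = 1, layer = "plasma"),
                    class = "stage_profiles")
  for (lk in c("average", "complete")) {
    dend <- hierarchical_cluster(prof, linkage = lk)
    oracle <- agglomerate_oracle(z, linkage = lk)
    expect_equal(sort(dend$tree$height), sort(oracle$heights), tolerance = 1e-9)
    thr <- median(dend$tree$height)
    got <- cut_at_threshold(dend, thr)$labels[rownames(z)]
    want <- agglomerate_oracle(z, linkage = lk, threshold = thr)$labels
    expect_equal(mclust::adjustedRandIndex(got, want), 1)
  }
})

test_that("threshold 0 gives singletons and a cut above the root gives one cluster", {
  cfg <- tiny_config()
  prof <- zscore_profiles(generate_stage_profiles(cfg))
  dend <- hierarchical_cluster(prof)
  all1 <- cut_at_threshold(dend, max(dend$tree$height) * 1.01)
  expect_equal(all1$k, 1L)
  singles <- cut_at_threshold(dend, 0)
  expect_equal(singles$k, nrow(prof$z))
  expect_equal(sum(cut_at_threshold(dend, 1.0)$sizes), nrow(prof$z))
})

test_that("cluster labels are invariant to input row permutation", {
  cfg <- tiny_config()
  prof <- zscore_profiles(generate_stage_profiles(cfg))
  set.seed(2)
  perm <- sample(nrow(prof$z))
  prof_p <- prof
  prof_p$z <- prof$z[perm, , drop = FALSE]
  prof_p$gene_symbol <- prof$gene_symbol[perm]
  thr <- 1.2
  a <- cut_at_threshold(hierarchical_cluster(prof), thr)$labels
  b <- cut_at_threshold(hierarchical_cluster(prof_p), thr)$labels
  expect_identical(a, b[names(a)])
})

test_that("lowering the threshold only refines clusters", {
  cfg <- tiny_config()
  prof <- zscore_profiles(generate_stage_profiles(cfg))
  dend <- hierarchical_cluster(prof)
  coarse <- cut_at_threshold(dend, 1.5)$labels
  fine <- cut_at_threshold(dend, 0.8)$labels
  expect_gte(max(fine), max(coarse))
  # every fine cluster sits inside exactly one coarse cluster
  split_tab <- table(fine, coarse[names(fine)])
  expect_true(all(rowSums(split_tab > 0) == 1))
})

test_that("labels are ordered by cluster size and summaries recover archetypes", {
  cfg <- tiny_config(seed = 21)
  tr <- generator_truth(cfg)
  prof <- zscore_profiles(generate_stage_profiles(cfg, tr))
  dend <- hierarchical_cluster(prof)
  asn <- cut_at_threshold(dend, threshold_for_k(dend, cfg$n_plasma_clusters))
  expect_equal(asn$sizes, sort(asn$sizes, decreasing = TRUE))
  expect_equal(sum(asn$sizes), nrow(prof$z))

  summ <- cluster_profiles_summary(asn, prof)
  expect_equal(sum(summ$size), nrow(prof$z))
  # each recovered cluster mean is close to one planted archetype
  for (i in seq_len(nrow(summ))) {
    if (summ$size[i] < 5) next
    dists <- sqrt(colSums((t(tr$plasma_archetypes) -
                             as.numeric(summ[i, c("I", "II", "III", "IV")]))^2))
    expect_lt(min(dists), 3 * cfg$noise_sd / sqrt(summ$size[i]) + 0.2)
  }

  # degenerate summaries: one big cluster averages to the global mean
  one <- cut_at_threshold(dend, max(dend$tree$height) * 1.01)
  s1 <- cluster_profiles_summary(one, prof)
  expect_equal(as.numeric(s1[1, c("I", "II", "III", "IV")]),
               unname(colMeans(prof$z)), tolerance = 1e-9)
})
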