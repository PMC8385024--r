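toy_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  out <- data.frame(gene = toupper(genes), score = scores,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

test_that("annotation enrichment reduces to EF 1 when foreground is the background", {
  bg <- sprintf("G%02d", 1:40)
  sets <- list(list(name = "S1", description = "", members = bg[1:10]),
               list(name = "S2", description = "", members = bg[5:30]))
  res <- fisher_annotation_enrichment(bg, bg, sets)
  expect_equal(res$ef, c(1, 1))
  expect_equal(res$p, c(1, 1))
  expect_error(fisher_annotation_enrichment(c(bg, "ZZ"), bg, sets), "subset")
})

test_that("an exact foreground hit yields EF = bg/fg ratio with enumeration p", {
  bg <- sprintf("G%03d", 1:100)
  sets <- list(list(name = "HIT", description = "", members = bg[1:10]))
  res <- fisher_annotation_enrichment(bg[1:10], bg, sets)
  expect_equal(res$ef, 10)
  expect_equal(res$p, hyper_tail_oracle(10, 10, 10, 100), tolerance = 1e-12)
})

test_that("a planted annotation ranks first among decoys", {
  set.seed(12)
  bg <- sprintf("G%03d", 1:300)
  deps <- bg[1:40]
  sets <- c(list(list(name = "PLANTED", description = "", members = bg[1:35])),
            lapply(1:8, function(i) list(name = paste0("DECOY", i),
                                         description = "",
                                         members = sample(bg, 30))))
  res <- fisher_annotation_enrichment(deps, bg, sets)
  expect_equal(res$set[1], "PLANTED")
  expect_true(res$significant[1])
})

test_that("signal-to-noise scores match hand computation with the sd floor", {
  v <- rbind(up = c(3, 4, 5, 0, 1, 2),
             flat = c(1, 1.1, 0.9, 1, 1.05, 0.95),
             down = c(0, 1, 0.5, 4, 5, 4.5),
             shifted = c(2.5, 2, 2.25, 0.5, 0, 0.25),
             noisy = c(5, -5, 0, 1, 2, -3))
  colnames(v) <- c(paste0("a", 1:3), paste0("b", 1:3))
  qm <- quant_matrix(v, layer = "tissue", scale = "log2")
  rk <- rank_by_signal_to_noise(qm, paste0("a", 1:3), paste0("b", 1:3))
  hand <- apply(v, 1, function(r) {
    ma <- mean(r[1:3]); mb <- mean(r[4:6])
    fa <- max(sd(r[1:3]), 0.2 * abs(ma), 0.2)
    fb <- max(sd(r[4:6]), 0.2 * abs(mb), 0.2)
    (ma - mb) / (fa + fb)
  })
  expect_equal(setNames(rk$score, rk$gene),
               sort(hand, decreasing = TRUE), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rk$gene[1], "shifted")

  # identical groups score zero everywhere
  same <- quant_matrix(cbind(v[, 1:3], v[, 1:3] ),
                       layer = "tissue", scale = "log2")
  colnames(same$values) <- c(paste0("a", 1:3), paste0("b", 1:3))
  rk0 <- rank_by_signal_to_noise(same, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(rk0$score, rep(0, nrow(v)))
})

test_that("enrichment score matches the exhaustive running-sum oracle", {
  set.seed(5)
  scores <- round(rnorm(10), 2)
  rk <- toy_ranked(scores)
  members <- rk$gene[c(2, 5, 9)]
  for (p in c(0, 1, 2)) {
    es <- gsea_es(rk, members, p = p)
    expect_equal(es$es, es_oracle(rk$gene, rk$score, members, p = p),
                 tolerance = 1e-12)
  }
  # single hit at the head with p = 0 gives ES = 1
  expect_equal(gsea_es(rk, rk$gene[1], p = 0)$es, 1)
  # the whole list as a set is maximally enriched
  expect_equal(gsea_es(rk, rk$gene, p = 1)$es, 1)
  # absent sets are NA
  expect_true(is.na(gsea_es(rk, c("ZZZ"), p = 1)$es))
})

test_that("running sum agrees with its closed-form extremes after zero-padding", {
  set.seed(6)
  rk <- toy_ranked(round(rnorm(8), 2))
  members <- rk$gene[c(1, 4)]
  padded <- toy_ranked(c(rk$score, 0, 0, 0),
                       c(rk$gene, "PAD1", "PAD2", "PAD3"))
  es_pad <- gsea_es(padded, members)
  expect_equal(es_pad$es, es_oracle(padded$gene, padded$score, members),
               tolerance = 1e-12)
  run <- gsea_running_sum(padded, members)
  expect_equal(max(abs(run)), abs(es_pad$es), tolerance = 1e-12)
})

test_that("weight zero reproduces the classic unweighted KS statistic", {
  rk <- toy_ranked(c(5, 4, 3, 2, 1, 0.5))
  members <- rk$gene[c(1, 2)]
  # hits at positions 1,2: running max = 2/2 - 0 = 1 at position 2
  expect_equal(gsea_es(rk, members, p = 0)$es, 1)
  members2 <- rk$gene[c(5, 6)]
  # all four misses first: -4/4, then recovery; extreme is -1 + eps region
  expect_equal(gsea_es(rk, members2, p = 0)$es,
               es_oracle(rk$gene, rk$score, members2, p = 0), tolerance = 1e-12)
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  scores <- sort(rnorm(50), decreasing = TRUE)
  rk <- toy_ranked(scores, sprintf("G%02d", 1:50))
  sets <- list(A = rk$gene[c(1, 3, 7, 20)], B = rk$gene[c(40, 45, 48)])
  stat_vec <- setNames(rk$score, rk$gene)
  for (nm in names(sets)) {
    mine <- gsea_es(rk, sets[[nm]], p = 1)$es
    ref <- fgsea::calcGseaStat(stat_vec, selectedStats = match(sets[[nm]], names(stat_vec)),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("reversing the group labels negates scores and enrichment signs", {
  two <- generate_two_group_matrix(n_genes = 60, n_a = 5, n_b = 5,
                                   planted_genes = sprintf("G%05d", 1:10),
                                   shift = 1.5, seed = 3)
  sa <- names(two$groups)[two$groups == "A"]
  sb <- names(two$groups)[two$groups == "B"]
  rk_ab <- rank_by_signal_to_noise(two$matrix, sa, sb)
  rk_ba <- rank_by_signal_to_noise(two$matrix, sb, sa)
  expect_equal(setNames(rk_ab$score, rk_ab$gene)[sort(rk_ab$gene)],
               -setNames(rk_ba$score, rk_ba$gene)[sort(rk_ba$gene)],
               tolerance = 1e-12)
  set_g <- sprintf("G%05d", 1:10)
  expect_equal(gsea_es(rk_ab, set_g)$es, -gsea_es(rk_ba, set_g)$es,
               tolerance = 1e-10)
})

test_that("permutation GSEA is deterministic and recovers a planted set", {
  set.seed(1)
  set_list <- c(list(PLANTED = sprintf("G%05d", 1:15)),
                lapply(setNames(1:5, paste0("R", 1:5)), function(i)
                  sprintf("G%05d", sample(16:200, 12))))
  two <- generate_two_group_matrix(n_genes = 200, n_a = 10, n_b = 10,
                                   planted_genes = set_list$PLANTED,
                                   shift = 1.2, seed = 9)
  r1 <- gsea_permutation(two$matrix, two$groups, set_list, n_perm = 100, seed = 42)
  r2 <- gsea_permutation(two$matrix, two$groups, set_list, n_perm = 100, seed = 42)
  expect_identical(r1, r2)
  expect_lt(r1$q_fdr[r1$set == "PLANTED"], 0.25)
  expect_gt(r1$nes[r1$set == "PLANTED"], 1)
})

test_that("tiny groups fall back to gene-set permutation with a warning", {
  two <- generate_two_group_matrix(n_genes = 80, n_a = 2, n_b = 2, seed = 2)
  sets <- list(S = sprintf("G%05d", 1:10))
  expect_warning(
    res <- gsea_permutation(two$matrix, two$groups, sets, n_perm = 100, seed = 1),
    "gene-set permutation")
  expect_true(is.finite(res$es[1]))
})
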