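anchor_qm <- function(vals, genes = "MMP2") {
  m <- matrix(vals, nrow = 1,
              dimnames = list("P1", sprintf("s%02d", seq_along(vals))))
  quant_matrix(m, gene_symbol = genes, layer = "tissue", scale = "log2")
}

test_that("median split sends the median sample to the low group", {
  sp <- split_by_median(anchor_qm(c(1, 2, 3, 4)))
  expect_equal(sp$high, c("s04", "s03"))
  expect_equal(sp$low, c("s02", "s01"))

  sp95 <- split_by_median(anchor_qm(seq_len(95)))
  expect_equal(length(sp95$high), 47L)
  expect_equal(length(sp95$low), 48L)
  expect_true(all(sp95$values[sp95$high] > stats::median(seq_len(95)) - 1))

  expect_warning(tied <- split_by_median(anchor_qm(rep(1, 6))), "constant")
  expect_equal(tied$high, paste0("s0", 1:3))
  expect_error(split_by_median(anchor_qm(1:10), anchor = "NOPE"), "not found")
  expect_error(split_by_median(anchor_qm(c(1, 2, NA, NA, NA))), "fewer than 4")
})

test_that("split sizes differ by at most one and respect the sorted order", {
  set.seed(3)
  for (n in c(7, 10, 23)) {
    sp <- split_by_median(anchor_qm(rnorm(n)))
    expect_lte(abs(length(sp$high) - length(sp$low)), 1L)
    expect_gte(min(sp$values[sp$high]), max(sp$values[sp$low]))
  }
})

test_that("spearman screen recovers identity, negation, and tie-broken ranks", {
  set.seed(8)
  a <- rnorm(20)
  v <- rbind(same = a, neg = -a, noise = rnorm(20))
  colnames(v) <- sprintf("s%02d", 1:20)
  qm <- quant_matrix(v, layer = "tissue", scale = "log2",
                     gene_symbol = c("SAME", "NEG", "NOISE"))
  scr <- spearman_screen(qm, setNames(a, colnames(v)))
  tab <- scr$table
  expect_equal(tab$rho[tab$key == "SAME"], 1)
  expect_equal(tab$rho[tab$key == "NEG"], -1)
  expect_lt(tab$p[tab$key == "SAME"], 1e-10)
  expect_equal(scr$n_positive_significant, 1L)

  # tie handling matches the average-rank Pearson oracle
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4)
  v2 <- matrix(x, 1, dimnames = list("P1", sprintf("s%d", 1:6)))
  qm2 <- quant_matrix(v2, layer = "tissue", scale = "log2")
  scr2 <- spearman_screen(qm2, setNames(y, colnames(v2)))
  expect_equal(scr2$table$rho, spearman_oracle(x, y), tolerance = 1e-12)
  expect_equal(scr2$table$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("spearman rho equals the rank oracle over exhaustive small inputs", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(5:8, 1)
    x <- sample(1:4, n, replace = TRUE) + stats::runif(n, 0, 0.01) * (i %% 2)
    y <- stats::rnorm(n)
    v <- matrix(x, 1, dimnames = list("P1", sprintf("s%d", seq_len(n))))
    qm <- quant_matrix(v, layer = "tissue", scale = "log2")
    got <- spearman_screen(qm, setNames(y, colnames(v)))$table$rho
    expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("ssGSEA with alpha 0 matches the cumulative-ECDF oracle on a toy", {
  expr <- c(A = 5, B = 4, C = 3, D = 2, E = 1, F = 0)
  members <- c("A", "C")
  m <- matrix(expr, ncol = 1, dimnames = list(names(expr), "s1"))
  qm <- quant_matrix(m, gene_symbol = names(expr), layer = "transcriptome",
                     scale = "log2")
  act <- regulon_activity(qm, list(TF = members), alpha = 0)
  expect_equal(unname(act$scores["TF", "s1"]),
               ssgsea_oracle_alpha0(expr, members), tolerance = 1e-12)
  # hand enumeration: hits at positions 1 and 3 of 6
  # P_in  = 1/2,1/2,1,1,1,1 ; P_out = 0,1/4,1/4,2/4,3/4,1
  expect_equal(unname(act$scores["TF", "s1"]),
               sum(c(1/2, 1/2, 1, 1, 1, 1) - c(0, 1/4, 1/4, 2/4, 3/4, 1)))
})

test_that("targets at the top of a sample maximize its regulon score", {
  set.seed(15)
  genes <- sprintf("G%02d", 1:12)
  members <- genes[1:4]
  base <- sort(rnorm(12), decreasing = TRUE)
  top <- matrix(base, ncol = 1, dimnames = list(genes, "s1"))
  qm_top <- quant_matrix(top, gene_symbol = genes, layer = "transcriptome",
                         scale = "log2")
  s_top <- regulon_activity(qm_top, list(TF = members), alpha = 0.25)$scores[1, 1]
  for (i in 1:25) {
    perm <- sample(12)
    qm_p <- quant_matrix(matrix(base[order(perm)], ncol = 1,
                                dimnames = list(genes, "s1")),
                         gene_symbol = genes, layer = "transcriptome",
                         scale = "log2")
    expect_gte(s_top + 1e-9,
               regulon_activity(qm_p, list(TF = members), alpha = 0.25)$scores[1, 1])
  }
})

test_that("regulon scores are invariant to monotone transforms of a sample", {
  cfg <- tiny_config()
  sim <- simulate_layers(cfg)
  expr <- sim$transcriptome
  warped <- expr
  warped$values <- exp(expr$values / 3) + 1    # strictly increasing
  a <- regulon_activity(expr, sim$regulons, alpha = 0.25)$scores
  b <- regulon_activity(warped, sim$regulons, alpha = 0.25)$scores
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a planted transcription factor correlates with the anchor", {
  cfg <- generator_config(seed = 7)
  tr <- generator_truth(cfg)
  ti <- generate_tissue_cohort(cfg, tr)
  tp <- generate_transcriptome_and_phospho(cfg, tr, ti)
  anchor <- split_by_median(ti)$values
  act <- regulon_activity(tp$transcriptome, tp$regulons, alpha = 0.25,
                          anchor_vector = anchor)
  expect_true(all(act$correlation$rho > 0))
  expect_true(all(act$correlation$p < 0.05))
  # an absent regulon yields an NA row, not an error
  suppressMessages(
    act2 <- regulon_activity(tp$transcriptome, list(GHOST = c("NOT", "HERE")),
                             alpha = 0.25))
  expect_true(all(is.na(act2$scores)))
})

test_that("KSEA matches its closed form and is antisymmetric under sign flip", {
  # constructed example: background exactly N(0, 0.5)-like discrete values
  lfc <- rep(c(-0.5, 0.5), each = 500)
  sites <- sprintf("S%04d", 1:1000)
  sub <- sites[1:25]
  lfc[1:25] <- 0.8
  ph <- data.frame(site_id = sites, log2fc = lfc, n = 3L)
  res <- ksea(ph, list(KIN = sub), min_substrates = 5)
  mean_all <- mean(lfc); sd_all <- sd(lfc)
  expect_equal(res$z, (0.8 - mean_all) * 5 / sd_all, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)

  flipped <- ph; flipped$log2fc <- -flipped$log2fc
  res_f <- ksea(flipped, list(KIN = sub), min_substrates = 5)
  expect_equal(res_f$z, -res$z, tolerance = 1e-12)

  # substrates at the background mean score zero
  ph0 <- data.frame(site_id = sites, log2fc = rep(c(-1, 1), 500), n = 1L)
  res0 <- ksea(ph0, list(NULLKIN = sites[1:50]), min_substrates = 5)
  expect_equal(res0$z, 0)

  expect_error(ksea(data.frame(site_id = sites, log2fc = 0, n = 1L),
                    list(KIN = sub)), "zero variance")
  expect_error(ksea(ph, list(KIN = sub[1:3]), min_substrates = 5), "minimum substrate")
})

test_that("phospho fold changes between groups feed KSEA consistently", {
  set.seed(30)
  v <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(sprintf("S%03d", 1:200), sprintf("p%02d", 1:10)))
  v[1:20, 1:5] <- v[1:20, 1:5] + 1
  fc <- phospho_fold_changes(v, high = sprintf("p%02d", 1:5),
                             low = sprintf("p%02d", 6:10))
  expect_equal(nrow(fc), 200L)
  expect_gt(mean(fc$log2fc[1:20]), 0.5)
  res <- ksea(fc, list(KIN = sprintf("S%03d", 1:20)), min_substrates = 5)
  expect_gt(res$z[1], 3)
})
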