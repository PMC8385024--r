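#' Restrict two labelled analyte sets to their common universe
#'
#' @param assign_a,assign_b named vectors (analyte key -> label), e.g.
#'   cluster labels and secretome categories keyed on harmonized ids.
#' @return list with `universe` (common keys, sorted), `a`, `b` (restricted
#'   assignments).
#' @export
common_universe <- function(assign_a, assign_b) {
  if (is.null(names(assign_a)) || is.null(names(assign_b)))
    stop("assignments must be named by analyte key")
  universe <- sort(intersect(names(assign_a), names(assign_b)))
  if (length(universe) == 0L)
    stop("empty universe: the two assignments share no analyte keys")
  list(universe = universe, a = assign_a[universe], b = assign_b[universe])
}

#' Fisher enrichment of a 2x2 overlap
#'
#' For an overlap of `k` analytes between a group of size `K` and a
#' category of size `n` within a universe of size `N`, the enrichment
#' factor is the observed/expected ratio EF = (k*N)/(K*n) and the p-value
#' is the hypergeometric tail of the 2x2 table (one-sided `greater` by
#' default; `two_sided` uses Fisher's exact test).
#'
#' @param k,K,n,N contingency counts with k <= min(K, n) and K, n <= N.
#' @param alternative `"greater"` (enrichment) or `"two_sided"`.
#' @return list with `ef` and `p`. `ef` is `NA` when `K` or `n` is 0, and 0
#'   when `k` is 0 (so depleted cells stay visible).
#' @export
fisher_enrichment <- function(k, K, n, N, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N ||
      k < K + n - N)
    stop("invalid contingency counts")
  if (K == 0 || n == 0) return(list(ef = NA_real_, p = NA_real_))
  ef <- (k * N) / (K * n)
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2))$p.value
  }
  list(ef = ef, p = min(1, p))
}

#' Fisher association matrix between two assignments
#'
#' One Fisher enrichment test per (label of A) x (label of B) pair over the
#' common universe, with Benjamini-Hochberg adjustment across all pairs of
#' the panel (a single FDR family per matrix).
#'
#' @inheritParams common_universe
#' @param fdr significance cutoff on the BH q-value (default 0.02).
#' @param alternative passed to [fisher_enrichment()].
#' @return data.frame: cluster, category, k, K, n, N, ef, p, q, significant.
#' @export
association_matrix <- function(assign_a, assign_b, fdr = 0.02,
                               alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cu <- common_universe(assign_a, assign_b)
  a <- cu$a; b <- cu$b
  N <- length(cu$universe)
  la <- sort(unique(a)); lb <- sort(unique(b))
  grid <- expand.grid(cluster = la, category = lb, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ia <- a == grid$cluster[i]; ib <- b == grid$category[i]
    fe <- fisher_enrichment(sum(ia & ib), sum(ia), sum(ib), N, alternative)
    data.frame(cluster = grid$cluster[i], category = grid$category[i],
               k = sum(ia & ib), K = sum(ia), n = sum(ib), N = N,
               ef = fe$ef, p = fe$p)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr
  rownames(res) <- NULL
  res
}

#' Multi-way set intersection with Venn region counts
#'
#' @param sets list of >= 2 character vectors (analyte keys).
#' @param names optional set names.
#' @return list with `signature` (the all-way intersection, sorted),
#'   `regions` (data.frame: one row per non-empty membership pattern with
#'   its exclusive count), `names`.
#' @export
intersect_signature <- function(sets, names = NULL) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names)) names <- if (!is.null(base::names(sets)))
    base::names(sets) else paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  pattern <- apply(memb, 1, function(r) paste(ifelse(r, "1", "0"), collapse = ""))
  counts <- table(pattern)
  regions <- data.frame(pattern = base::names(counts),
                        count = as.integer(counts), stringsAsFactors = FALSE)
  regions <- regions[order(regions$pattern, decreasing = TRUE), , drop = FALSE]
  rownames(regions) <- NULL
  signature <- universe[rowSums(memb) == length(sets)]
  list(signature = signature, regions = regions, names = names)
}

#' Load the packaged 16-protein plasma/secretome verification table
#'
#' A published table of 16 proteins whose secretion drops under MMP2
#' knockdown and whose plasma levels rise from TNM stage I to II; columns
#' are accession, gene, the four stage z-scores, the mean log2(KD/control)
#' SILAC ratio and its p-value.
#' @return data.frame with 16 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "protlayers",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Verify the packaged 16-protein table against the selection rules
#'
#' Applies the category-1 rule (log2 ratio <= -log2(1.5)), the stage I to
#' II increase rule (z_II > z_I), and checks each row's four z-scores sum
#' to zero within a rounding tolerance.
#'
#' @param table1 the fixture (default: [load_table1()]).
#' @param zsum_tol tolerance on the z-score row sum (default 0.02,
#'   two-decimal rounding of four entries).
#' @return list with `n_category1`, `n_stage_increase`, `n_zsum_ok`,
#'   `n_rows`, and a per-row `diagnostics` data.frame.
#' @export
table1_reproduction <- function(table1 = load_table1(), zsum_tol = 0.02) {
  need <- c("accession", "gene", "z_I", "z_II", "z_III", "z_IV", "log2fc", "p")
  if (!all(need %in% names(table1))) stop("fixture is missing required columns")
  cat1 <- table1$log2fc <= -log2(1.5)
  rise <- table1$z_II > table1$z_I
  zsum <- rowSums(table1[, c("z_I", "z_II", "z_III", "z_IV")])
  zok <- abs(zsum) <= zsum_tol + 1e-9
  diagnostics <- data.frame(accession = table1$accession, gene = table1$gene,
                            category1 = cat1, stage_increase = rise,
                            z_sum = zsum, z_sum_ok = zok,
                            stringsAsFactors = FALSE)
  list(n_rows = nrow(table1), n_category1 = sum(cat1),
       n_stage_increase = sum(rise), n_zsum_ok = sum(zok),
       diagnostics = diagnostics)
}
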