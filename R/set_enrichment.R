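#' Fisher annotation enrichment of a foreground against a background
#'
#' Classic 2x2 over-representation: per gene set S, k = |fg n S|,
#' K = |fg|, n = |bg n S|, N = |bg|; enrichment factor (k*N)/(K*n) and a
#' one-sided hypergeometric p, BH-adjusted across sets.
#'
#' @param foreground character vector of gene symbols (must be a subset of
#'   `background`).
#' @param background character vector of gene symbols (the tested universe).
#' @param sets list of gene sets as returned by [read_gmt()], or a named
#'   list of character vectors.
#' @param fdr BH q cutoff for the `significant` flag (default 0.02).
#' @param alternative passed to [fisher_enrichment()].
#' @return data.frame: set, k, K, n, N, ef, p, q, significant; ordered by q
#'   then p.
#' @export
fisher_annotation_enrichment <- function(foreground, background, sets,
                                         fdr = 0.02,
                                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  foreground <- unique(toupper(foreground))
  background <- unique(toupper(background))
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  members <- lapply(sets, function(s) if (is.list(s)) s$members else toupper(s))
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- vapply(sets, function(s)
      if (is.list(s)) s$name else "", character(1))
  K <- length(foreground); N <- length(background)
  res <- do.call(rbind, lapply(names(members), function(nm) {
    inset <- intersect(members[[nm]], background)
    fe <- fisher_enrichment(length(intersect(foreground, inset)), K,
                            length(inset), N, alternative)
    data.frame(set = nm, k = length(intersect(foreground, inset)), K = K,
               n = length(inset), N = N, ef = fe$ef, p = fe$p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr
  res <- res[order(res$q, res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# vectorized signal-to-noise scores with the standard sd floor
s2n_scores <- function(values, ia, ib, min_obs = 3) {
  ga <- values[, ia, drop = FALSE]; gb <- values[, ib, drop = FALSE]
  na_ <- rowSums(!is.na(ga)); nb_ <- rowSums(!is.na(gb))
  ma <- rowMeans(ga, na.rm = TRUE); mb <- rowMeans(gb, na.rm = TRUE)
  sa <- apply(ga, 1, stats::sd, na.rm = TRUE)
  sb <- apply(gb, 1, stats::sd, na.rm = TRUE)
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2, na.rm = TRUE)
  score <- (ma - mb) / (floor_sd(sa, ma) + floor_sd(sb, mb))
  score[na_ < min_obs | nb_ < min_obs] <- NA
  score
}

#' Rank genes by signal-to-noise between two sample groups
#'
#' Score = (meanA - meanB) / (sdA + sdB) with each sd floored at
#' max(0.2*|mean|, 0.2), the conventional two-class GSEA metric. Missing
#' values are ignored per gene; genes with fewer than `min_obs` observed
#' samples in either group are dropped. High scores mean up in group A.
#'
#' @param x a `quant_matrix`.
#' @param group_a,group_b sample labels of the two groups (>= 3 each).
#' @param metric `"s2n"` (default) or `"log2fc"` (plain mean difference).
#' @param min_obs minimum observed samples per group per gene.
#' @param min_group minimum samples per group (default 3; the permutation
#'   driver relaxes this in its gene-set fallback mode).
#' @return a `ranked_list` data.frame (gene, score), ordered by descending
#'   score with lexicographic tie-break.
#' @export
rank_by_signal_to_noise <- function(x, group_a, group_b,
                                    metric = c("s2n", "log2fc"), min_obs = 3,
                                    min_group = 3) {
  stopifnot(inherits(x, "quant_matrix"))
  metric <- match.arg(metric)
  ia <- match(group_a, colnames(x$values)); ib <- match(group_b, colnames(x$values))
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample labels")
  if (length(ia) < min_group || length(ib) < min_group)
    stop(sprintf("need >= %d samples per group", min_group))
  genes <- analyte_keys(x)
  score <- if (metric == "s2n") {
    s2n_scores(x$values, ia, ib, min_obs)
  } else {
    ga <- x$values[, ia, drop = FALSE]; gb <- x$values[, ib, drop = FALSE]
    s <- rowMeans(ga, na.rm = TRUE) - rowMeans(gb, na.rm = TRUE)
    s[rowSums(!is.na(ga)) < min_obs | rowSums(!is.na(gb)) < min_obs] <- NA
    s
  }
  keep <- !is.na(score) & !duplicated(genes)
  out <- data.frame(gene = genes[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score of a gene set
#'
#' The standard weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, set members increment the running sum by |score|^p
#' (normalized to the hit total) and non-members decrement it by
#' 1/(N - n_hits); ES is the running-sum extreme of largest magnitude.
#'
#' @param ranked a `ranked_list` from [rank_by_signal_to_noise()].
#' @param set a gene set (list with `members`, or character vector).
#' @param p weight exponent (default 1; 0 gives the classic unweighted KS).
#' @return list with `es`, `n_hits`, `leading_edge`. `es` is `NA` when no
#'   set member is in the list.
#' @export
gsea_es <- function(ranked, set, p = 1) {
  members <- if (is.list(set)) set$members else toupper(set)
  genes <- ranked$gene
  N <- length(genes)
  pos <- which(genes %in% members)
  m <- length(pos)
  if (m == 0L) return(list(es = NA_real_, n_hits = 0L, leading_edge = character(0)))
  w <- abs(ranked$score[pos])^p
  if (sum(w) <= 0) w <- rep(1, m)    # all-zero hit scores: fall back to equal weights
  cumw <- cumsum(w) / sum(w)
  if (m == N) {       # every gene a hit: running sum peaks at 1 at the end
    return(list(es = 1, n_hits = m, leading_edge = genes))
  }
  dec <- (pos - seq_len(m)) / (N - m)  # misses accumulated before each hit
  post <- cumw - dec                   # running sum just after each hit
  pre <- c(0, cumw[-m]) - dec          # running sum just before each hit
  up <- max(post); dn <- min(pre)
  if (up >= abs(dn)) {
    peak <- which.max(post)
    list(es = up, n_hits = m, leading_edge = genes[pos[seq_len(peak)]])
  } else {
    peak <- which.min(pre)
    list(es = dn, n_hits = m, leading_edge = genes[pos[peak:m]])
  }
}

#' Full running sum of the enrichment statistic (for inspection/plots)
#'
#' @inheritParams gsea_es
#' @return numeric vector of length `nrow(ranked)`: the running sum after
#'   each position.
#' @export
gsea_running_sum <- function(ranked, set, p = 1) {
  members <- if (is.list(set)) set$members else toupper(set)
  hit <- ranked$gene %in% members
  N <- length(hit); m <- sum(hit)
  if (m == 0L) stop("no set members in the ranked list")
  w <- abs(ranked$score)^p
  inc <- numeric(N)
  if (sum(w[hit]) > 0) inc[hit] <- w[hit] / sum(w[hit]) else inc[hit] <- 1 / m
  if (m < N) inc[!hit] <- -1 / (N - m)
  cumsum(inc)
}

#' Two-group permutation GSEA
#'
#' Phenotype-label permutation of the standard two-class GSEA: the
#' signal-to-noise ranking and per-set enrichment scores are recomputed for
#' `n_perm` random relabelings; NES divides each ES by the mean magnitude
#' of same-sign permutation scores, the nominal p is the same-sign tail
#' fraction, and the FDR follows the pooled positive/negative NES
#' procedure. When either group has fewer than 3 samples the test falls
#' back to gene-set permutation with a warning.
#'
#' @param x a `quant_matrix`.
#' @param groups named character vector sample -> group (exactly 2 groups);
#'   the first group in sorted order plays "group A" (high scores up in A).
#' @param sets list of gene sets ([read_gmt()] style or named character
#'   vectors).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (required: permutations are the only randomness).
#' @param weight_p ES weight exponent (default 1).
#' @param fdr FDR cutoff for the `significant` flag (default 0.25).
#' @return data.frame: set, size, es, nes, p_nominal, q_fdr, significant,
#'   leading_edge (comma-separated).
#' @export
gsea_permutation <- function(x, groups, sets, n_perm = 1000, seed,
                             weight_p = 1, fdr = 0.25) {
  stopifnot(inherits(x, "quant_matrix"), n_perm >= 100)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  groups <- groups[colnames(x$values)]
  if (anyNA(groups)) stop("groups must cover every sample")
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  sa <- names(groups)[groups == lev[1]]; sb <- names(groups)[groups == lev[2]]
  member_list <- lapply(sets, function(s) if (is.list(s)) s$members else toupper(s))
  if (is.null(names(member_list)))
    names(member_list) <- vapply(sets, function(s)
      if (is.list(s)) s$name else "set", character(1))

  phenotype_ok <- min(length(sa), length(sb)) >= 3
  ranked <- rank_by_signal_to_noise(x, sa, sb,
                                    min_obs = if (phenotype_ok) 3 else 1,
                                    min_group = if (phenotype_ok) 3 else 2)
  obs <- lapply(member_list, function(mm) gsea_es(ranked, mm, p = weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")

  phenotype <- phenotype_ok
  if (!phenotype)
    warning("group size < 3: falling back to gene-set permutation")
  n_sets <- length(member_list)
  perm_es <- matrix(NA_real_, n_sets, n_perm)
  if (phenotype) {
    all_s <- colnames(x$values)
    for (r in seq_len(n_perm)) {
      pa <- sample(all_s, length(sa))
      rk <- rank_by_signal_to_noise(x, pa, setdiff(all_s, pa))
      perm_es[, r] <- vapply(member_list, function(mm)
        gsea_es(rk, mm, p = weight_p)$es, numeric(1))
    }
  } else {
    sizes <- vapply(member_list, function(mm) sum(ranked$gene %in% mm), integer(1))
    for (r in seq_len(n_perm)) {
      perm_es[, r] <- vapply(sizes, function(sz) {
        if (sz == 0) return(NA_real_)
        gsea_es(ranked, sample(ranked$gene, sz), p = weight_p)$es
      }, numeric(1))
    }
  }

  nes <- p_nom <- rep(NA_real_, n_sets)
  nes_perm <- matrix(NA_real_, n_sets, n_perm)
  for (i in seq_len(n_sets)) {
    pe <- perm_es[i, ]
    pos <- pe[!is.na(pe) & pe >= 0]; neg <- pe[!is.na(pe) & pe < 0]
    if (length(pos)) nes_perm[i, !is.na(pe) & pe >= 0] <- pos / mean(pos)
    if (length(neg)) nes_perm[i, !is.na(pe) & pe < 0] <- neg / -mean(neg)
    if (is.na(es[i])) next
    if (es[i] >= 0) {
      if (length(pos)) { nes[i] <- es[i] / mean(pos); p_nom[i] <- mean(pos >= es[i]) }
    } else {
      if (length(neg)) { nes[i] <- -es[i] / mean(neg); p_nom[i] <- mean(neg <= es[i]) }
    }
  }
  # pooled-NES FDR (positive and negative branches separately)
  q <- rep(NA_real_, n_sets)
  all_perm <- as.numeric(nes_perm); all_perm <- all_perm[!is.na(all_perm)]
  for (i in seq_len(n_sets)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- mean(all_perm[all_perm >= 0] >= nes[i])
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      num <- mean(all_perm[all_perm < 0] <= nes[i])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    q[i] <- if (is.nan(num) || is.nan(den) || den == 0) NA_real_ else min(1, num / den)
  }
  data.frame(set = names(member_list),
             size = vapply(obs, `[[`, integer(1), "n_hits"),
             es = es, nes = nes, p_nominal = p_nom, q_fdr = q,
             significant = !is.na(q) & q < fdr,
             leading_edge = vapply(obs, function(o)
               paste(o$leading_edge, collapse = ","), character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
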