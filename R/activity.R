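#' Split samples by the median abundance of an anchor protein
#'
#' Samples with an observed anchor value are sorted by decreasing
#' abundance (ties broken by sample label); the top floor(n/2) form the
#' high group, the rest (including the median sample at odd n) the low
#' group, so a 95-sample cohort splits 47 high / 48 low.
#'
#' @param x a `quant_matrix`.
#' @param anchor gene symbol (or accession) of the anchor protein
#'   (default `"MMP2"`).
#' @return a `group_split`: list with `anchor`, `high`, `low` (sample
#'   label vectors), `values` (anchor abundances used).
#' @export
split_by_median <- function(x, anchor = "MMP2") {
  stopifnot(inherits(x, "quant_matrix"))
  ix <- match(anchor, analyte_keys(x))
  if (is.na(ix)) ix <- match(anchor, rownames(x$values))
  if (is.na(ix)) stop(sprintf("anchor '%s' not found", anchor))
  v <- x$values[ix, ]
  v <- v[!is.na(v)]
  if (length(v) < 4L) stop("anchor observed in fewer than 4 samples")
  if (stats::sd(v) < 1e-12) warning("anchor is constant; split follows sample label order")
  ord <- names(v)[order(-v, names(v))]
  n_high <- floor(length(v) / 2)
  structure(list(anchor = anchor, high = ord[seq_len(n_high)],
                 low = ord[(n_high + 1):length(v)], values = v),
            class = "group_split")
}

# Spearman rho (average ranks) with t-approximation p, pairwise-complete
spearman_one <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 5L) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  c(rho = rho, p = min(1, p), n = n)
}

#' Spearman correlation screen against an anchor profile
#'
#' Per analyte: Spearman's rho (Pearson on average ranks) against the
#' anchor vector with pairwise-complete observations and a t-approximation
#' p-value. Reports the count of positively and significantly correlated
#' analytes (rho > 0, p < alpha).
#'
#' @param x a `quant_matrix`.
#' @param anchor_vector named numeric vector (sample -> anchor abundance),
#'   e.g. `split_by_median(x)$values`.
#' @param alpha significance cutoff for the positive-correlation count.
#' @return list with `table` (data.frame: key, rho, p, n) and
#'   `n_positive_significant`.
#' @export
spearman_screen <- function(x, anchor_vector, alpha = 0.05) {
  stopifnot(inherits(x, "quant_matrix"))
  common <- intersect(colnames(x$values), names(anchor_vector))
  if (length(common) < 5L) stop("fewer than 5 shared samples")
  v <- x$values[, common, drop = FALSE]
  a <- anchor_vector[common]
  res <- t(apply(v, 1, spearman_one, y = a))
  tab <- data.frame(key = analyte_keys(x), rho = res[, "rho"], p = res[, "p"],
                    n = as.integer(res[, "n"]), stringsAsFactors = FALSE,
                    row.names = NULL)
  list(table = tab,
       n_positive_significant = sum(!is.na(tab$rho) & tab$rho > 0 &
                                      tab$p < alpha, na.rm = TRUE))
}

# single-sample enrichment score for one sample's expression vector
ssgsea_one <- function(expr, hit, alpha) {
  ok <- !is.na(expr)
  r <- rank(expr[ok])                    # higher expression -> higher rank
  h <- hit[ok]
  ord <- order(-r)                       # walk from highest expression down
  r <- r[ord]; h <- h[ord]
  m <- sum(h); N <- length(h)
  if (m == 0L || m == N) return(NA_real_)
  w <- r^alpha
  p_in <- cumsum(ifelse(h, w, 0)) / sum(w[h])
  p_out <- cumsum(!h) / (N - m)
  sum(p_in - p_out)
}

#' Transcription-factor regulon activity by single-sample GSEA
#'
#' For each sample, genes are ranked by expression and each regulon gets
#' the rank-weighted cumulative ECDF difference between its targets and
#' all other genes (weight exponent `alpha`, no cross-sample
#' renormalization). Being rank-based, scores are invariant to any
#' strictly increasing transform of a sample's expression values. When an
#' anchor profile is supplied, each factor's activity is additionally
#' correlated (Spearman) with it across samples.
#'
#' @param expr a transcriptome `quant_matrix` (log2(x+1) scale expected).
#' @param regulons named list TF -> character vector of target symbols.
#' @param alpha rank-weight exponent (default 0.25).
#' @param anchor_vector optional named numeric vector (sample -> anchor
#'   abundance) for the correlation column.
#' @return an `activity_scores` list: `scores` (TF x sample matrix; NA row
#'   when no target is expressed) and `correlation` (data.frame tf, rho, p,
#'   n_targets; NULL without an anchor).
#' @export
regulon_activity <- function(expr, regulons, alpha = 0.25, anchor_vector = NULL) {
  stopifnot(inherits(expr, "quant_matrix"), alpha >= 0)
  genes <- analyte_keys(expr)
  scores <- matrix(NA_real_, length(regulons), ncol(expr$values),
                   dimnames = list(names(regulons), colnames(expr$values)))
  n_targets <- integer(length(regulons))
  for (i in seq_along(regulons)) {
    hit <- genes %in% toupper(regulons[[i]])
    n_targets[i] <- sum(hit)
    if (n_targets[i] == 0L) {
      message(sprintf("regulon '%s': no expressed targets; scores set to NA",
                      names(regulons)[i]))
      next
    }
    scores[i, ] <- apply(expr$values, 2, ssgsea_one, hit = hit, alpha = alpha)
  }
  correlation <- NULL
  if (!is.null(anchor_vector)) {
    common <- intersect(colnames(scores), names(anchor_vector))
    correlation <- do.call(rbind, lapply(seq_along(regulons), function(i) {
      sp <- spearman_one(scores[i, common], anchor_vector[common])
      data.frame(tf = names(regulons)[i], rho = sp[["rho"]], p = sp[["p"]],
                 n_targets = n_targets[i], stringsAsFactors = FALSE)
    }))
  }
  structure(list(scores = scores, correlation = correlation, alpha = alpha),
            class = "activity_scores")
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' The mean-substrate z-score: for a kinase with m quantified substrate
#' sites of mean log2 fold change `mean_sub`,
#' z = (mean_sub - mean_all) * sqrt(m) / sd_all, where `mean_all`/`sd_all`
#' are over all quantified sites. Two-sided normal p, BH q. Kinases with
#' fewer than `min_substrates` quantified sites are excluded.
#'
#' @param phospho data.frame with columns `site_id`, `log2fc`, `n`
#'   (per-site observation count).
#' @param kinase_map named list kinase -> character vector of site ids.
#' @param min_substrates minimum quantified substrate count (default 5).
#' @param min_sites minimum total quantified sites for a stable background
#'   (default 50).
#' @return data.frame: kinase, m, mean_sub, z, p, q; ordered by |z|
#'   descending.
#' @export
ksea <- function(phospho, kinase_map, min_substrates = 5, min_sites = 50) {
  need <- c("site_id", "log2fc", "n")
  if (!all(need %in% names(phospho))) stop("phospho table needs site_id, log2fc, n")
  if (any(!is.finite(phospho$log2fc))) stop("fold changes must be finite")
  if (any(phospho$n < 1)) stop("per-site observation counts must be >= 1")
  if (nrow(phospho) < min_sites)
    stop(sprintf("need at least %d quantified sites for a stable background", min_sites))
  mean_all <- mean(phospho$log2fc)
  sd_all <- stats::sd(phospho$log2fc)
  if (sd_all < 1e-12) stop("degenerate input: zero variance across sites")
  lfc <- stats::setNames(phospho$log2fc, phospho$site_id)
  res <- do.call(rbind, lapply(names(kinase_map), function(kin) {
    sub <- intersect(unique(kinase_map[[kin]]), phospho$site_id)
    m <- length(sub)
    if (m < min_substrates) return(NULL)
    mean_sub <- mean(lfc[sub])
    z <- (mean_sub - mean_all) * sqrt(m) / sd_all
    data.frame(kinase = kin, m = m, mean_sub = mean_sub, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  if (is.null(res)) stop("no kinase reached the minimum substrate count")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(-abs(res$z)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Phosphosite fold changes between two sample groups
#'
#' Convenience for building a KSEA input from a per-sample phosphosite
#' matrix: per site, mean(high) - mean(low) with pairwise-complete
#' observations, plus the observation count.
#'
#' @param values numeric matrix sites x samples (log2 scale).
#' @param high,low sample label vectors.
#' @return data.frame: site_id, log2fc, n.
#' @export
phospho_fold_changes <- function(values, high, low) {
  stopifnot(is.matrix(values))
  hi <- values[, intersect(high, colnames(values)), drop = FALSE]
  lo <- values[, intersect(low, colnames(values)), drop = FALSE]
  lfc <- rowMeans(hi, na.rm = TRUE) - rowMeans(lo, na.rm = TRUE)
  n <- rowSums(!is.na(hi)) + rowSums(!is.na(lo))
  keep <- is.finite(lfc) & n >= 1
  data.frame(site_id = rownames(values)[keep], log2fc = lfc[keep],
             n = as.integer(n[keep]), stringsAsFactors = FALSE, row.names = NULL)
}
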