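#' Construct a SILAC replicate set
#'
#' Holds per-protein log2(H/L) ratios across replicates together with each
#' replicate's label orientation. In forward replicates the knockdown
#' condition carries the heavy label, so log2(H/L) = log2(KD/control); in
#' reverse replicates the labels are swapped and the raw ratio has the
#' opposite sign.
#'
#' @param ratios numeric matrix of log2(H/L), proteins x replicates;
#'   rownames are accessions; `NA` marks unobserved cells.
#' @param orientation character vector, one of `"forward"`/`"reverse"` per
#'   replicate column.
#' @param gene_symbol optional gene symbols per protein.
#' @return a `silac_replicate_set`.
#' @export
silac_replicate_set <- function(ratios, orientation, gene_symbol = NULL) {
  if (!is.matrix(ratios) || !is.numeric(ratios)) stop("'ratios' must be a numeric matrix")
  if (length(orientation) != ncol(ratios))
    stop("one orientation per replicate column required")
  if (!all(orientation %in% c("forward", "reverse")))
    stop("unknown orientation; must be 'forward' or 'reverse'")
  if (is.null(rownames(ratios))) stop("'ratios' must have accession rownames")
  if (any(rowSums(!is.na(ratios)) == 0))
    warning("some proteins have no observed replicate")
  if (is.null(gene_symbol)) gene_symbol <- rep("", nrow(ratios))
  structure(list(ratios = ratios, orientation = orientation,
                 gene_symbol = toupper(gene_symbol)),
            class = "silac_replicate_set")
}

#' Orient raw SILAC ratios to log2(KD/control)
#'
#' Forward replicates pass through; reverse replicates are negated.
#'
#' @param reps a `silac_replicate_set`.
#' @return numeric matrix of oriented log2(KD/control) ratios.
#' @export
orient_ratios <- function(reps) {
  stopifnot(inherits(reps, "silac_replicate_set"))
  s <- ifelse(reps$orientation == "forward", 1, -1)
  oriented <- sweep(reps$ratios, 2, s, `*`)
  attr(oriented, "gene_symbol") <- reps$gene_symbol
  oriented
}

#' Aggregate oriented replicate ratios into per-protein statistics
#'
#' Proteins observed in fewer than `min_obs` replicates are flagged
#' non-quantifiable: they stay in the table (identification lists) but are
#' excluded from testing and adjustment. Quantifiable proteins get the
#' replicate mean and sd, a two-sided one-sample t-test of the mean log2
#' ratio against 0, and Benjamini-Hochberg adjustment across all tested
#' proteins. Zero-variance proteins cannot be t-tested; their p is set to
#' the smallest representable double with a warning.
#'
#' @param oriented oriented ratio matrix from [orient_ratios()].
#' @param min_obs minimum observed replicates for quantifiability (>= 2).
#' @return a `secretome_stats` data.frame: accession, gene, n_obs, mean,
#'   sd, p, q, quantifiable.
#' @export
aggregate_replicates <- function(oriented, min_obs = 3) {
  stopifnot(is.matrix(oriented), min_obs >= 2)
  gene <- attr(oriented, "gene_symbol")
  if (is.null(gene)) gene <- rep("", nrow(oriented))
  n_obs <- rowSums(!is.na(oriented))
  if (any(n_obs == 0))
    message(sprintf("aggregate_replicates: %d protein(s) with zero observations dropped",
                    sum(n_obs == 0)))
  keep <- n_obs > 0
  oriented <- oriented[keep, , drop = FALSE]
  gene <- gene[keep]; n_obs <- n_obs[keep]
  mu <- rowMeans(oriented, na.rm = TRUE)
  sd_ <- apply(oriented, 1, stats::sd, na.rm = TRUE)
  quantifiable <- n_obs >= min_obs
  p <- rep(NA_real_, length(mu))
  degenerate <- quantifiable & !is.na(sd_) & sd_ < 1e-12
  testable <- quantifiable & !degenerate
  p[testable] <- vapply(which(testable), function(i)
    stats::t.test(oriented[i, ][!is.na(oriented[i, ])], mu = 0)$p.value,
    numeric(1))
  if (any(degenerate)) {
    warning(sprintf("%d protein(s) with zero replicate variance; p set to machine minimum",
                    sum(degenerate)))
    p[degenerate] <- .Machine$double.xmin
  }
  q <- rep(NA_real_, length(p))
  q[quantifiable] <- stats::p.adjust(p[quantifiable], method = "BH")
  res <- data.frame(accession = rownames(oriented), gene = gene,
                    n_obs = as.integer(n_obs), mean = mu, sd = sd_,
                    p = p, q = q, quantifiable = quantifiable,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("secretome_stats", "data.frame")
  res
}

#' Flag differentially secreted proteins
#'
#' A protein is called `down` when its mean oriented log2 ratio is at or
#' below `-log2(fc_threshold)` and its (raw or BH-adjusted) p-value is
#' below `alpha`; `up` symmetrically. Non-quantifiable proteins are never
#' flagged.
#'
#' @param stats a `secretome_stats` data.frame.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param alpha significance level (default 0.05).
#' @param use_adjusted use the BH q-value instead of the raw p.
#' @return `stats` with a `dep_flag` column in \{"up","down","none"\}.
#' @export
call_deps <- function(stats, fc_threshold = 1.5, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(stats, "secretome_stats"), fc_threshold >= 1)
  lfc <- log2(fc_threshold)
  sig <- if (use_adjusted) stats$q else stats$p
  ok <- stats$quantifiable & !is.na(sig) & sig < alpha
  stats$dep_flag <- ifelse(ok & stats$mean <= -lfc, "down",
                           ifelse(ok & stats$mean >= lfc, "up", "none"))
  stats
}

#' Assign the three secretome fold-change categories
#'
#' Category 1: mean log2(KD/control) at or below -log2(1.5) (secretion
#' decreased by knockdown); category 3: at or above +log2(1.5); category 2
#' otherwise. Boundary values go to the extreme category. Categories use
#' the fold change only, independent of significance.
#'
#' @param stats a `secretome_stats` data.frame.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @return `stats` with a `category` column (1, 2, or 3; NA when not
#'   quantifiable).
#' @export
categorize <- function(stats, fc_threshold = 1.5) {
  stopifnot(inherits(stats, "secretome_stats"))
  lfc <- log2(fc_threshold)
  cat_ <- ifelse(stats$mean <= -lfc, 1L, ifelse(stats$mean >= lfc, 3L, 2L))
  cat_[!stats$quantifiable] <- NA_integer_
  stats$category <- cat_
  stats
}

#' Write a SILAC replicate set as tab-delimited text
#'
#' Columns: accession, gene, one ratio column per replicate named
#' `<orientation>_rep<i>` so the orientation round-trips.
#' @param reps a `silac_replicate_set`.
#' @param path output path.
#' @export
write_silac <- function(reps, path) {
  stopifnot(inherits(reps, "silac_replicate_set"))
  m <- reps$ratios
  colnames(m) <- sprintf("%s_rep%d", reps$orientation, seq_len(ncol(m)))
  df <- data.frame(accession = rownames(m), gene = reps$gene_symbol,
                   as.data.frame(m, optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a SILAC replicate set written by [write_silac()]
#' @param path file path.
#' @return a `silac_replicate_set`.
#' @export
read_silac <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  rep_cols <- grep("^(forward|reverse)_rep", names(df), value = TRUE)
  if (length(rep_cols) == 0L) stop("no replicate columns found")
  m <- as.matrix(df[rep_cols])
  rownames(m) <- df$accession
  orientation <- sub("_rep.*$", "", rep_cols)
  silac_replicate_set(m, orientation, gene_symbol = df$gene)
}
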