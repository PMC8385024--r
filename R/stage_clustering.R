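#' Collapse a per-sample matrix to per-stage means
#'
#' For each protein, the mean over samples of each TNM stage, ignoring
#' missing values. Proteins with no observation in some stage are dropped
#' (and reported), not imputed.
#'
#' @param x a `quant_matrix` with `stage` labels covering every sample.
#' @return a `quant_matrix` with columns I..IV (only stages present).
#' @export
collapse_to_stage_means <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (is.null(x$stage)) stop("stage_of_sample is not defined")
  stages <- c("I", "II", "III", "IV")
  stages <- stages[stages %in% x$stage]
  if (length(stages) == 0L) stop("no stage has any sample")
  if (identical(colnames(x$values), stages)) return(x)
  means <- vapply(stages, function(s)
    rowMeans(x$values[, x$stage == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x$values)))
  means[is.nan(means)] <- NA
  complete <- stats::complete.cases(means)
  if (!all(complete))
    message(sprintf("collapse_to_stage_means: dropped %d protein(s) with an unobserved stage",
                    sum(!complete)))
  out <- x
  out$values <- means[complete, , drop = FALSE]
  out$gene_symbol <- x$gene_symbol[complete]
  out$stage <- stats::setNames(stages, stages)
  out$group <- NULL
  out
}

#' Z-score stage profiles per protein
#'
#' Each complete row is centred and scaled to mean 0, sd 1 across the
#' stages (divisor `n - ddof`). Constant rows and rows with any missing
#' stage are excluded and reported, never zero-filled.
#'
#' @param x a 4-column (stage) `quant_matrix`.
#' @param ddof degrees-of-freedom correction, 0 or 1 (default 1, sample sd).
#' @return a `stage_profiles` object: list with `z` (matrix, one row per
#'   retained analyte), `gene_symbol`, and `dropped` (data.frame with
#'   accession and reason).
#' @export
zscore_profiles <- function(x, ddof = 1) {
  stopifnot(inherits(x, "quant_matrix"), ddof %in% c(0, 1))
  v <- x$values
  n <- ncol(v)
  complete <- stats::complete.cases(v)
  sds <- apply(v, 1, stats::sd)                    # divisor n-1
  if (ddof == 0) sds <- sds * sqrt((n - 1) / n)
  constant <- complete & (is.na(sds) | sds < 1e-12)
  keep <- complete & !constant
  dropped <- data.frame(
    accession = rownames(v)[!keep],
    reason = ifelse(constant[!keep], "constant", "incomplete"),
    stringsAsFactors = FALSE)
  z <- (v[keep, , drop = FALSE] - rowMeans(v[keep, , drop = FALSE])) / sds[keep]
  structure(list(z = z, gene_symbol = x$gene_symbol[keep], dropped = dropped,
                 ddof = ddof, layer = x$layer),
            class = "stage_profiles")
}

#' @export
print.stage_profiles <- function(x, ...) {
  cat(sprintf("stage_profiles: %d analytes x %d stages (%d dropped)\n",
              nrow(x$z), ncol(x$z), nrow(x$dropped)))
  invisible(x)
}

#' Agglomerative clustering of stage profiles
#'
#' Euclidean-distance agglomeration of z-profiles. Rows are sorted by
#' analyte key before clustering so the merge sequence (and hence the
#' labels) is invariant to input row order; distance ties are then resolved
#' by that fixed order.
#'
#' @param profiles a `stage_profiles` object.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`
#'   (Ward on squared Euclidean distances, `ward.D2`).
#' @return a `profile_dendrogram`: list with the `hclust` tree, ordered
#'   `keys`, the `profiles` rows in tree order, and `linkage`.
#' @export
hierarchical_cluster <- function(profiles, linkage = c("average", "complete", "ward")) {
  stopifnot(inherits(profiles, "stage_profiles"))
  linkage <- match.arg(linkage)
  if (nrow(profiles$z) < 2L) stop("need at least two profiles to cluster")
  keys <- rownames(profiles$z)
  ord <- order(keys)
  z <- profiles$z[ord, , drop = FALSE]
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = method)
  structure(list(tree = hc, keys = keys[ord], z = z,
                 gene_symbol = profiles$gene_symbol[ord], linkage = linkage),
            class = "profile_dendrogram")
}

#' Cut a dendrogram at a distance threshold
#'
#' Clusters are the connected components formed by merges with height
#' strictly below the threshold. Cluster ids are relabelled 1..k by
#' decreasing size, ties broken by the smallest member key, so labels are
#' deterministic.
#'
#' @param dend a `profile_dendrogram`.
#' @param threshold merge-height cutoff (>= 0).
#' @return a `cluster_assignment`: list with `labels` (named integer
#'   vector analyte -> cluster), `threshold`, `linkage`, `merge_heights`,
#'   `k`, `sizes`.
#' @export
cut_at_threshold <- function(dend, threshold) {
  stopifnot(inherits(dend, "profile_dendrogram"), threshold >= 0)
  hc <- dend$tree
  n <- length(dend$keys)
  k <- n - sum(hc$height < threshold)
  raw <- stats::cutree(hc, k = k)
  labels <- relabel_by_size(raw, dend$keys)
  structure(list(labels = labels, threshold = threshold, linkage = dend$linkage,
                 merge_heights = hc$height, k = max(labels),
                 sizes = as.integer(table(labels))),
            class = "cluster_assignment")
}

# relabel clusters 1..k by decreasing size; ties by smallest member key
relabel_by_size <- function(raw, keys) {
  names(raw) <- keys
  sizes <- table(raw)
  minkey <- vapply(split(keys, raw), min, character(1))
  ord <- order(-as.integer(sizes), minkey)
  new_id <- integer(length(sizes))
  new_id[as.integer(names(sizes)[ord])] <- seq_along(ord)
  stats::setNames(new_id[raw], keys)
}

#' Smallest threshold band yielding k clusters
#'
#' Returns a threshold that, under the strict "merge heights below
#' threshold" rule of [cut_at_threshold()], yields exactly `k` clusters:
#' the midpoint of the gap between the (n-k)-th and (n-k+1)-th merge
#' heights. This is the calibrated analogue of choosing a fixed distance
#' cutoff so a tree yields a target cluster count.
#'
#' @param dend a `profile_dendrogram`.
#' @param k target number of clusters.
#' @return a threshold value.
#' @export
threshold_for_k <- function(dend, k) {
  stopifnot(inherits(dend, "profile_dendrogram"))
  h <- sort(dend$tree$height)
  n <- length(dend$keys)
  stopifnot(k >= 1, k <= n)
  lo <- if (k == n) 0 else h[n - k]
  hi <- if (k == 1) h[n - 1] * 1.01 + 1e-9 else h[n - k + 1]
  (lo + hi) / 2
}

#' Per-cluster mean z-profiles and sizes
#'
#' @param assignment a `cluster_assignment`.
#' @param profiles the `stage_profiles` the assignment was built from.
#' @return data.frame: cluster, size, one mean-z column per stage.
#' @export
cluster_profiles_summary <- function(assignment, profiles) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(profiles, "stage_profiles"))
  z <- profiles$z[names(assignment$labels), , drop = FALSE]
  cl <- assignment$labels
  out <- do.call(rbind, lapply(sort(unique(cl)), function(ci) {
    zi <- z[cl == ci, , drop = FALSE]
    data.frame(cluster = ci, size = nrow(zi), t(colMeans(zi)))
  }))
  names(out)[-(1:2)] <- colnames(z)
  rownames(out) <- NULL
  out
}
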