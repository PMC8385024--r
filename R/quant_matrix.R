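#' Construct a quantitative abundance matrix
#'
#' The central container of the package: a features x samples abundance
#' matrix with a layer tag (plasma, tissue, secretome, transcriptome),
#' optional gene symbols alongside the accession key, optional TNM-stage and
#' group labels per sample, and an explicit missingness mask. Missing cells
#' are stored as `NA` in `values`; they are never silently zero.
#'
#' @param values numeric matrix; rownames are analyte accessions, colnames
#'   are sample labels. `NA` marks missing observations.
#' @param gene_symbol optional character vector of gene symbols, one per row
#'   (empty string when unknown). Uppercased on construction.
#' @param layer one of `"plasma"`, `"tissue"`, `"secretome"`,
#'   `"transcriptome"`.
#' @param scale `"log2"` or `"linear"`, declaring the scale of `values`.
#' @param stage optional named character vector mapping sample -> TNM stage
#'   (`"I"`..`"IV"`).
#' @param group optional named character vector mapping sample -> group.
#' @return an object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, gene_symbol = NULL,
                         layer = c("plasma", "tissue", "secretome", "transcriptome"),
                         scale = c("log2", "linear"),
                         stage = NULL, group = NULL) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || any(!nzchar(rownames(values))))
    stop("'values' must have non-empty rownames (accessions)")
  if (is.null(colnames(values)) || ncol(values) == 0L)
    stop("'values' must have at least one named sample column")
  if (anyDuplicated(rownames(values)))
    stop("duplicate accessions; collapse before constructing (see read_quant_matrix)")
  if (is.null(gene_symbol)) gene_symbol <- rep("", nrow(values))
  if (length(gene_symbol) != nrow(values))
    stop("'gene_symbol' must have one entry per row")
  gene_symbol <- toupper(ifelse(is.na(gene_symbol), "", gene_symbol))
  if (!is.null(stage)) {
    stage <- stage[colnames(values)]
    if (anyNA(stage)) stop("'stage' must cover every sample")
    if (!all(stage %in% c("I", "II", "III", "IV")))
      stop("stages must be in {I, II, III, IV}")
    names(stage) <- colnames(values)
  }
  if (!is.null(group)) {
    group <- group[colnames(values)]
    if (anyNA(group)) stop("'group' must cover every sample")
    names(group) <- colnames(values)
  }
  structure(
    list(values = values, gene_symbol = gene_symbol, layer = layer,
         scale = scale, stage = stage, group = group),
    class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s, %s scale]: %d analytes x %d samples (%.1f%% missing)\n",
              x$layer, x$scale, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  if (!is.null(x$stage))
    cat("  stages:", paste(sprintf("%s=%d", names(table(x$stage)), table(x$stage)),
                           collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Missingness mask of a quant_matrix
#' @param x a `quant_matrix`.
#' @return logical matrix, `TRUE` where the observation is missing.
#' @export
missing_mask <- function(x) is.na(x$values)

#' Join key per analyte
#'
#' Cross-layer equality is on gene symbol when both sides carry one, with the
#' accession as fallback — symbols are the only key stable across search
#' engines and data sources.
#' @param x a `quant_matrix`.
#' @param join_on `"gene_symbol"` (symbol with accession fallback) or
#'   `"accession"`.
#' @return character vector of keys, one per row of `x`.
#' @export
analyte_keys <- function(x, join_on = c("gene_symbol", "accession")) {
  join_on <- match.arg(join_on)
  acc <- rownames(x$values)
  if (join_on == "accession") return(acc)
  ifelse(nzchar(x$gene_symbol), x$gene_symbol, acc)
}

#' Read a tab-delimited quantitative matrix
#'
#' Expected layout: header row; first column analyte accession; optional
#' second column gene symbol (detected as non-numeric); remaining columns
#' one per sample. Empty cells, `NA` and `NaN` are masked as missing, as is
#' `0` on linear-scale data when `zero_as_missing` (label-free search
#' engines emit 0 for non-detection). Duplicate accessions are collapsed to
#' the row with the largest total intensity.
#'
#' @param path file path.
#' @inheritParams quant_matrix
#' @param zero_as_missing mask exact zeros as missing; defaults to `TRUE`
#'   for linear-scale data.
#' @param stage,group optional sample annotations, passed through.
#' @return a `quant_matrix`.
#' @export
read_quant_matrix <- function(path, layer, scale = c("log2", "linear"),
                              zero_as_missing = NULL, stage = NULL, group = NULL) {
  scale <- match.arg(scale)
  if (is.null(zero_as_missing)) zero_as_missing <- scale == "linear"
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = c())
  if (ncol(raw) < 2L) stop("malformed header: need accession plus at least one sample column")
  acc <- trimws(raw[[1L]])
  if (any(!nzchar(acc))) stop("empty accession in column 1")
  to_num <- function(col) suppressWarnings(as.numeric(ifelse(
    trimws(col) %in% c("", "NA", "NaN", "nan"), NA, trimws(col))))
  col2 <- to_num(raw[[2L]])
  # gene column iff the second column is non-numeric text (possibly with blanks)
  has_gene <- all(is.na(col2)) && any(nzchar(trimws(raw[[2L]])))
  gene <- if (has_gene) trimws(raw[[2L]]) else rep("", nrow(raw))
  first_sample <- if (has_gene) 3L else 2L
  if (first_sample > ncol(raw)) stop("zero sample columns")
  vals <- vapply(raw[first_sample:ncol(raw)], to_num, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, colnames(raw)[first_sample:ncol(raw)]))
  if (zero_as_missing) vals[!is.na(vals) & vals == 0] <- NA
  # collapse duplicate accessions: keep the row with max total intensity
  if (anyDuplicated(acc)) {
    tot <- rowSums(vals, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(acc), acc), function(ix)
      ix[which.max(tot[ix])]), use.names = FALSE)
    keep <- sort(keep)
    acc <- acc[keep]; gene <- gene[keep]; vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- acc
  quant_matrix(vals, gene_symbol = gene, layer = layer, scale = scale,
               stage = stage, group = group)
}

#' Write a quant_matrix as tab-delimited text
#'
#' Inverse of [read_quant_matrix()]: accession, gene symbol (if any), one
#' column per sample; missing cells written as `NA`.
#' @param x a `quant_matrix`.
#' @param path output path.
#' @export
write_quant_matrix <- function(x, path) {
  df <- data.frame(accession = rownames(x$values), stringsAsFactors = FALSE)
  if (any(nzchar(x$gene_symbol))) df$gene <- x$gene_symbol
  df <- cbind(df, as.data.frame(x$values, optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name TAB description TAB member TAB member ...
#' Members are uppercased and deduplicated.
#' @param path GMT file path.
#' @return named list of gene sets, each a list with `name`, `description`,
#'   `members` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i))
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT format error at line %d: empty member list", i))
    list(name = f[[1L]], description = f[[2L]], members = members)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets in GMT format
#' @param sets list of gene sets as produced by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read transcription-factor regulons from a TF-target edge table
#'
#' Tab-delimited with header: `tf`, `target`, `is_predicted` (0/1). Edges
#' flagged as computationally predicted are removed when
#' `exclude_predicted`, mirroring curated-evidence-only regulon use.
#' Self-edges (tf == target) are dropped with a warning.
#'
#' @param path edge table path.
#' @param exclude_predicted drop predicted edges (default `TRUE`).
#' @return named list: per TF a character vector of target symbols.
#' @export
read_regulons <- function(path, exclude_predicted = TRUE) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("tf", "target", "is_predicted") %in% names(df)))
    stop("regulon table must have columns tf, target, is_predicted")
  df$tf <- toupper(df$tf); df$target <- toupper(df$target)
  self <- df$tf == df$target
  if (any(self)) {
    warning(sprintf("dropped %d self-edge(s)", sum(self)))
    df <- df[!self, , drop = FALSE]
  }
  if (exclude_predicted) df <- df[df$is_predicted == 0, , drop = FALSE]
  lapply(split(df$target, df$tf), unique)
}

#' Harmonize analyte identifiers across layers
#'
#' Restricts two or more matrices to their common key space (gene symbol
#' with accession fallback, or accession) and reports pairwise overlap
#' counts. Within-matrix key collisions are resolved by keeping the row
#' with the highest mean abundance. Input matrices are not modified.
#'
#' @param matrices named list of `quant_matrix` objects (>= 2).
#' @param join_on `"gene_symbol"` or `"accession"`.
#' @return list with `matrices` (restricted, rows ordered by key),
#'   `universe` (common keys), `overlap` (pairwise overlap count matrix).
#' @export
harmonize_ids <- function(matrices, join_on = c("gene_symbol", "accession")) {
  join_on <- match.arg(join_on)
  if (length(matrices) < 2L) stop("need at least two matrices")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("layer", seq_along(matrices))
  keyed <- lapply(matrices, function(m) {
    k <- analyte_keys(m, join_on)
    if (anyDuplicated(k)) {
      mu <- rowMeans(m$values, na.rm = TRUE)
      keep <- unlist(lapply(split(seq_along(k), k), function(ix)
        ix[which.max(mu[ix])]), use.names = FALSE)
      keep <- sort(keep)
      m$values <- m$values[keep, , drop = FALSE]
      m$gene_symbol <- m$gene_symbol[keep]
      k <- k[keep]
    }
    list(m = m, keys = k)
  })
  keysets <- lapply(keyed, `[[`, "keys")
  p <- length(keysets)
  overlap <- matrix(0L, p, p, dimnames = list(names(matrices), names(matrices)))
  for (i in seq_len(p)) for (j in seq_len(p))
    overlap[i, j] <- length(intersect(keysets[[i]], keysets[[j]]))
  universe <- Reduce(intersect, keysets)
  if (length(universe) == 0L)
    stop("empty key overlap across layers: identifier spaces do not match")
  universe <- sort(universe)
  restricted <- lapply(keyed, function(kk) {
    ix <- match(universe, kk$keys)
    m <- kk$m
    m$values <- m$values[ix, , drop = FALSE]
    m$gene_symbol <- m$gene_symbol[ix]
    m
  })
  names(restricted) <- names(matrices)
  list(matrices = restricted, universe = universe, overlap = overlap)
}
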