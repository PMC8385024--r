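# Independent brute-force oracles used to check the package implementations.

# small generator configuration for fast tests
tiny_config <- function(seed = 11, ...) {
  generator_config(n_plasma = 120, n_secretome = 100, n_tissue = 150,
                   n_shared_plasma_secretome = 60, n_plasma_clusters = 5,
                   n_tissue_clusters = 6, n_tissue_samples = 24,
                   n_transcriptome = 300, n_phosphosites = 300,
                   n_kinases = 5, substrates_per_kinase = 20, seed = seed, ...)
}

# Benjamini-Hochberg by direct sort / cummin definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# upper hypergeometric tail by explicit enumeration over the support
hyper_tail_oracle <- function(k, K, n, N) {
  lo <- max(0L, K + n - N); hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(max(k, lo):hi, function(i)
    choose(n, i) * choose(N - n, K - i) / choose(N, K), numeric(1)))
}

# naive O(n^3) agglomeration with average or complete linkage;
# returns merge heights and the membership after cutting below `threshold`
agglomerate_oracle <- function(z, linkage = "average", threshold = Inf) {
  clusters <- lapply(seq_len(nrow(z)), identity)
  heights <- numeric(0)
  d <- as.matrix(dist(z))
  cluster_dist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    if (linkage == "average") mean(vals) else max(vals)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dd < best[1]) best <- c(dd, j, i)
    }
    heights <- c(heights, best[1])
    if (best[1] >= threshold) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(nrow(z))
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  list(heights = heights, labels = labels)
}

# full running-sum GSEA enrichment statistic, position by position
es_oracle <- function(genes, scores, members, p = 1) {
  hit <- genes %in% members
  N <- length(genes); m <- sum(hit)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / m
    } else -1 / (N - m)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# unweighted ssGSEA score by direct double loop over ranks (alpha = 0)
ssgsea_oracle_alpha0 <- function(expr, members) {
  genes <- names(expr)
  ord <- genes[order(-rank(expr))]
  hit <- ord %in% members
  m <- sum(hit); N <- length(ord)
  sum(cumsum(hit) / m - cumsum(!hit) / (N - m))
}

# Spearman rho via explicit average ranks and the Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
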