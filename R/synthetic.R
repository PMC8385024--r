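#' Configuration for the multi-layer synthetic data generator
#'
#' Defaults emulate the study design the pipeline targets: a 4-stage pooled
#' plasma proteome with 11 trend clusters, a 6-replicate forward/reverse
#' SILAC knockdown secretome with a planted down-regulated co-secretion
#' module, a 95-patient stage-labelled tissue cohort with 16 trend clusters,
#' a matched transcriptome carrying regulon signal for five focal-adhesion
#' transcription factors, and a phosphoproteome with one kinase whose
#' substrates shift between anchor-high and anchor-low patient groups.
#'
#' @param n_plasma,n_secretome,n_tissue proteins per layer.
#' @param n_shared_plasma_secretome genes planted as common to the plasma
#'   and secretome layers (the cross-layer universe).
#' @param n_plasma_clusters,n_tissue_clusters planted archetype counts.
#' @param noise_sd per-entry Gaussian noise on z-profile scale.
#' @param missing_rate completely-at-random missingness fraction (plasma).
#' @param n_replicates SILAC replicates; the first half run forward
#'   (knockdown heavy), the second half reverse.
#' @param silac_noise_sd per-replicate noise on log2 ratios.
#' @param dropout_rate per-cell missingness in the SILAC table.
#' @param planted_effect true log2(KD/control) of planted module proteins;
#'   must be <= -log2(1.5) so the module is category 1 by construction.
#' @param fraction_planted fraction of secretome proteins in the module.
#' @param n_tissue_samples tissue cohort size.
#' @param stage_props tissue stage proportions (names I..IV).
#' @param patient_sd per-patient global shift (log2 units).
#' @param n_transcriptome transcriptome gene count.
#' @param regulon_size targets per transcription factor.
#' @param tf_rho target Spearman-scale correlation between latent TF
#'   activity and the anchor protein across samples.
#' @param expr_noise_sd expression noise (log2 units).
#' @param n_kinases,substrates_per_kinase,n_phosphosites phospho layer sizes.
#' @param kinase_shift log2 fold-change shift of the active kinase's
#'   substrates between anchor-high and anchor-low groups.
#' @param site_noise_sd per-site fold-change noise.
#' @param seed root seed; per-layer child seeds are derived from it.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_plasma = 1000, n_secretome = 800, n_tissue = 1200,
                             n_shared_plasma_secretome = 523,
                             n_plasma_clusters = 11, n_tissue_clusters = 16,
                             noise_sd = 0.3, missing_rate = 0.05,
                             n_replicates = 6, silac_noise_sd = 0.25,
                             dropout_rate = 0.1, planted_effect = -1.0,
                             fraction_planted = 0.1,
                             n_tissue_samples = 95,
                             stage_props = c(I = 0.25, II = 0.30, III = 0.30, IV = 0.15),
                             patient_sd = 0.2,
                             n_transcriptome = 2000, regulon_size = 25,
                             tf_rho = 0.8, expr_noise_sd = 1,
                             n_kinases = 10, substrates_per_kinase = 25,
                             n_phosphosites = 1000, kinase_shift = 0.8,
                             site_noise_sd = 0.5, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_plasma, n_secretome, n_tissue, n_shared_plasma_secretome,
              n_plasma_clusters, n_tissue_clusters, n_replicates,
              n_tissue_samples, n_transcriptome, regulon_size, n_kinases,
              substrates_per_kinase, n_phosphosites)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (noise_sd <= 0 || silac_noise_sd <= 0 || site_noise_sd <= 0)
    stop("noise sds must be > 0")
  if (fraction_planted <= 0 || fraction_planted >= 1)
    stop("fraction_planted must be in (0,1)")
  if (missing_rate < 0 || missing_rate >= 1 || dropout_rate < 0 || dropout_rate >= 1)
    stop("missing_rate/dropout_rate must be in [0,1)")
  if (n_plasma_clusters > n_plasma || n_tissue_clusters > n_tissue)
    stop("more clusters than proteins")
  if (n_shared_plasma_secretome > min(n_plasma, n_secretome, n_tissue))
    stop("shared gene count exceeds a layer size")
  if (planted_effect > -log2(1.5))
    stop("planted_effect must be <= -log2(1.5) so the module is category 1")
  if (!setequal(names(stage_props), c("I", "II", "III", "IV")) ||
      abs(sum(stage_props) - 1) > 1e-8)
    stop("stage_props must be named I..IV and sum to 1")
  if (n_kinases * substrates_per_kinase > n_phosphosites)
    stop("kinase substrates exceed total phosphosites")
  structure(cfg, class = "generator_config")
}

# child seed per layer, kept within 32-bit integer range
child_seed <- function(seed, k) as.integer((as.double(seed) + 104729 * k) %% 2147483647)

#' Stage-trend archetype profiles
#'
#' Returns `k` z-scored 4-stage profiles (row mean 0, sample sd 1) spread
#' near-uniformly over the sphere of valid z-profiles via a Fibonacci
#' lattice, then rotated so that archetype 1 is a sharp stage I to II riser
#' (the trend of the module the pipeline is built to recover).
#'
#' @param k number of archetypes.
#' @return k x 4 matrix, columns I..IV.
#' @export
stage_archetypes <- function(k) {
  stopifnot(k >= 1)
  # orthonormal basis of the mean-zero subspace of R^4
  B <- cbind(c(1, -1, 0, 0) / sqrt(2),
             c(1, 1, -2, 0) / sqrt(6),
             c(1, 1, 1, -3) / sqrt(12))
  # Fibonacci lattice on the unit 2-sphere
  i <- seq_len(k) - 0.5
  zc <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - zc^2))
  th <- pi * (1 + sqrt(5)) * (seq_len(k) - 1)
  U <- cbind(r * cos(th), r * sin(th), zc)
  # rotate so point 1 matches the sharp I->II rise trend
  tgt <- c(-1, 1.5, -0.3, -0.2)
  tgt <- (tgt - mean(tgt)) / stats::sd(tgt)
  tc <- as.numeric(crossprod(B, tgt)) / sqrt(3)
  v <- U[1, ] - tc
  if (sum(v^2) > 1e-12) {
    H <- diag(3) - 2 * tcrossprod(v) / sum(v^2)
    U <- U %*% t(H)
  }
  A <- sqrt(3) * U %*% t(B)
  colnames(A) <- c("I", "II", "III", "IV")
  rownames(A) <- paste0("archetype", seq_len(k))
  A
}

#' Build the ground-truth skeleton for a simulation
#'
#' Deterministically lays out the gene universe, layer memberships, cluster
#' labels, the planted co-secretion module, secretome effects, active
#' transcription factors and kinases. All structure sizes depend only on the
#' configuration; the seed only shuffles which genes take which role.
#'
#' @param config a [generator_config()].
#' @return a `generator_truth` list.
#' @export
generator_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, 0L))
  n_genes <- config$n_plasma + config$n_secretome + config$n_tissue
  genes <- sprintf("G%05d", seq_len(n_genes))
  module_size <- round(config$fraction_planted * config$n_secretome)
  # shared plasma/secretome genes; module plus MMP2 live inside them,
  # and all shared genes are also measured in tissue
  n_shared <- config$n_shared_plasma_secretome
  shared <- c("MMP2", sample(genes, n_shared - 1L))
  rest <- setdiff(genes, shared)
  module <- setdiff(shared, "MMP2")[seq_len(module_size)]
  plasma_only <- rest[seq_len(config$n_plasma - n_shared)]
  rest <- setdiff(rest, plasma_only)
  secretome_only <- rest[seq_len(config$n_secretome - n_shared)]
  rest <- setdiff(rest, secretome_only)
  tissue_only <- rest[seq_len(config$n_tissue - n_shared)]
  plasma_genes <- c(shared, plasma_only)
  secretome_genes <- c(shared, secretome_only)
  tissue_genes <- c(shared, tissue_only)

  assign_clusters <- function(gns, k) {
    lab <- integer(length(gns)); names(lab) <- gns
    planted <- gns %in% c(module, "MMP2")
    lab[planted] <- 1L
    lab[!planted] <- sample(rep_len(seq_len(k), sum(!planted)))
    lab
  }
  plasma_cluster <- assign_clusters(plasma_genes, config$n_plasma_clusters)
  tissue_cluster <- assign_clusters(tissue_genes, config$n_tissue_clusters)

  # the knockdown target itself loses secretion along with the module
  secretome_effect <- stats::setNames(numeric(length(secretome_genes)), secretome_genes)
  secretome_effect[c(module, "MMP2")] <- config$planted_effect

  # stage labels for the tissue cohort (largest-remainder rounding)
  n_s <- config$n_tissue_samples
  raw <- config$stage_props[c("I", "II", "III", "IV")] * n_s
  cnt <- floor(raw)
  extra <- order(raw - cnt, decreasing = TRUE)[seq_len(n_s - sum(cnt))]
  cnt[extra] <- cnt[extra] + 1L
  stage <- rep(c("I", "II", "III", "IV"), times = cnt)
  samples <- sprintf("PT%03d", seq_len(n_s))
  names(stage) <- samples

  tfs <- c("ETS1", "JUN", "KLF8", "NFKB1", "YBX1")
  target_pool <- sprintf("T%04d", seq_len(config$n_transcriptome))
  regulons <- lapply(seq_along(tfs), function(i)
    target_pool[((i - 1) * config$regulon_size + 1):(i * config$regulon_size)])
  names(regulons) <- tfs

  kinases <- c("SRC", "JNK1", "MTOR", "CDK1", "CSNK2A1", "AKT1", "MAPK1",
               "GSK3B", "PRKACA", "CAMK2A")[seq_len(config$n_kinases)]
  sites <- sprintf("P%05d_S%03d", seq_len(config$n_phosphosites),
                   sample(1:999, config$n_phosphosites, replace = TRUE))
  ks_map <- lapply(seq_along(kinases), function(i)
    sites[((i - 1) * config$substrates_per_kinase + 1):(i * config$substrates_per_kinase)])
  names(ks_map) <- kinases

  structure(list(
    plasma_genes = plasma_genes, secretome_genes = secretome_genes,
    tissue_genes = tissue_genes, shared_plasma_secretome = shared,
    planted_module = module,
    plasma_cluster = plasma_cluster, tissue_cluster = tissue_cluster,
    plasma_archetypes = stage_archetypes(config$n_plasma_clusters),
    tissue_archetypes = stage_archetypes(config$n_tissue_clusters),
    secretome_effect = secretome_effect,
    tissue_stage = stage, tissue_samples = samples,
    active_tfs = tfs, regulons = regulons,
    active_kinases = "SRC", kinase_map = ks_map, phosphosites = sites,
    seed = config$seed), class = "generator_truth")
}

# accession for a gene symbol: deterministic synthetic UniProt-style key
gene_accession <- function(genes) {
  acc <- sub("^[GT]", "Q", genes)
  ifelse(genes == "MMP2", "P08253", paste0(acc, "X"))
}

#' Simulate the pooled 4-stage plasma layer
#'
#' Each protein's profile is its cluster archetype plus i.i.d. Gaussian
#' noise, generated directly on the z-profile scale; a fraction of entries
#' is masked completely at random.
#'
#' @param config a [generator_config()].
#' @param truth a [generator_truth()]; built from `config` when `NULL`.
#' @param noise_sd,missing_rate override the config values (used by tests
#'   for zero-noise limits).
#' @return a plasma `quant_matrix` with columns I..IV.
#' @export
generate_stage_profiles <- function(config, truth = NULL,
                                    noise_sd = config$noise_sd,
                                    missing_rate = config$missing_rate) {
  if (is.null(truth)) truth <- generator_truth(config)
  set.seed(child_seed(config$seed, 1L))
  genes <- truth$plasma_genes
  lab <- truth$plasma_cluster[genes]
  vals <- truth$plasma_archetypes[lab, , drop = FALSE] +
    matrix(stats::rnorm(length(genes) * 4, 0, noise_sd), ncol = 4)
  if (missing_rate > 0)
    vals[matrix(stats::runif(length(vals)) < missing_rate, nrow(vals))] <- NA
  dimnames(vals) <- list(gene_accession(genes), c("I", "II", "III", "IV"))
  quant_matrix(vals, gene_symbol = genes, layer = "plasma", scale = "log2",
               stage = stats::setNames(c("I", "II", "III", "IV"), c("I", "II", "III", "IV")))
}

#' Simulate the forward/reverse SILAC secretome replicates
#'
#' Observed log2(H/L) per replicate is the orientation-signed true
#' knockdown effect plus noise: forward replicates (knockdown heavy) carry
#' the effect directly, reverse replicates carry its negation. Per-cell
#' dropout leaves some proteins below the quantifiability cutoff.
#'
#' @inheritParams generate_stage_profiles
#' @param silac_noise_sd,dropout_rate overrides for tests.
#' @return a `silac_replicate_set`: list with `ratios` (proteins x
#'   replicates, log2(H/L)), `orientation` per replicate, `gene_symbol`.
#' @export
generate_silac <- function(config, truth = NULL,
                           silac_noise_sd = config$silac_noise_sd,
                           dropout_rate = config$dropout_rate) {
  if (is.null(truth)) truth <- generator_truth(config)
  set.seed(child_seed(config$seed, 2L))
  genes <- truth$secretome_genes
  eff <- truth$secretome_effect[genes]
  nr <- config$n_replicates
  orientation <- rep(c("forward", "reverse"), times = c(ceiling(nr / 2), floor(nr / 2)))
  sign_r <- ifelse(orientation == "forward", 1, -1)
  ratios <- outer(eff, sign_r) +
    matrix(stats::rnorm(length(genes) * nr, 0, silac_noise_sd), ncol = nr)
  if (dropout_rate > 0)
    ratios[matrix(stats::runif(length(ratios)) < dropout_rate, nrow(ratios))] <- NA
  dimnames(ratios) <- list(gene_accession(genes), paste0("rep", seq_len(nr)))
  silac_replicate_set(ratios, orientation, gene_symbol = genes)
}

#' Simulate the stage-labelled tissue cohort
#'
#' Per-patient abundance is the protein's cluster archetype value at the
#' patient's stage, plus a patient-level shift and measurement noise. The
#' anchor protein MMP2 sits in the planted stage I to II riser cluster, so
#' its abundance drives the downstream high/low grouping.
#'
#' @inheritParams generate_stage_profiles
#' @param patient_sd override for tests.
#' @return a tissue `quant_matrix` with per-patient columns and stage labels.
#' @export
generate_tissue_cohort <- function(config, truth = NULL,
                                   noise_sd = config$noise_sd,
                                   patient_sd = config$patient_sd) {
  if (is.null(truth)) truth <- generator_truth(config)
  set.seed(child_seed(config$seed, 3L))
  genes <- truth$tissue_genes
  lab <- truth$tissue_cluster[genes]
  stage <- truth$tissue_stage
  samples <- truth$tissue_samples
  pat <- stats::rnorm(length(samples), 0, patient_sd)
  base <- truth$tissue_archetypes[lab, stage, drop = FALSE]
  vals <- base + rep(pat, each = length(genes)) +
    matrix(stats::rnorm(length(genes) * length(samples), 0, noise_sd),
           nrow = length(genes))
  dimnames(vals) <- list(gene_accession(genes), samples)
  quant_matrix(vals, gene_symbol = genes, layer = "tissue", scale = "log2",
               stage = stage)
}

#' Simulate the matched transcriptome and phosphoproteome
#'
#' A latent activity per transcription factor and sample is constructed to
#' correlate (population correlation `tf_rho`) with the anchor protein's
#' tissue abundance; targets of each factor get expression shifted by that
#' activity. Phosphosite fold changes between anchor-high and anchor-low
#' halves are centred at 0, except substrates of the active kinase, which
#' are shifted by `kinase_shift`.
#'
#' @inheritParams generate_stage_profiles
#' @param tissue the tissue `quant_matrix` (regenerated when `NULL`);
#'   supplies the anchor abundance driving the latent activities.
#' @param kinase_shift,tf_rho overrides for tests (null calibrations).
#' @return list with `transcriptome` (`quant_matrix`), `phospho`
#'   (data.frame: site_id, log2fc, n), `kinase_map`, `regulons`.
#' @export
generate_transcriptome_and_phospho <- function(config, truth = NULL, tissue = NULL,
                                               kinase_shift = config$kinase_shift,
                                               tf_rho = config$tf_rho) {
  if (is.null(truth)) truth <- generator_truth(config)
  if (is.null(tissue)) tissue <- generate_tissue_cohort(config, truth)
  set.seed(child_seed(config$seed, 4L))
  samples <- colnames(tissue$values)
  anchor <- tissue$values[match("MMP2", tissue$gene_symbol), ]
  az <- as.numeric(scale(anchor))
  n_s <- length(samples)

  genes <- sprintf("T%04d", seq_len(config$n_transcriptome))
  expr <- matrix(stats::rnorm(length(genes) * n_s, 5, config$expr_noise_sd),
                 nrow = length(genes), dimnames = list(paste0(genes, "X"), samples))
  activity <- matrix(NA_real_, length(truth$active_tfs), n_s,
                     dimnames = list(truth$active_tfs, samples))
  for (tf in truth$active_tfs) {
    act <- tf_rho * az + sqrt(max(0, 1 - tf_rho^2)) * stats::rnorm(n_s)
    activity[tf, ] <- act
    ix <- match(truth$regulons[[tf]], genes)
    expr[ix, ] <- expr[ix, ] + rep(act, each = length(ix))
  }
  transcriptome <- quant_matrix(expr, gene_symbol = genes, layer = "transcriptome",
                                scale = "log2", stage = tissue$stage)

  lfc <- stats::rnorm(config$n_phosphosites, 0, config$site_noise_sd)
  names(lfc) <- truth$phosphosites
  active_sites <- unlist(truth$kinase_map[truth$active_kinases], use.names = FALSE)
  lfc[active_sites] <- lfc[active_sites] + kinase_shift
  phospho <- data.frame(site_id = truth$phosphosites, log2fc = as.numeric(lfc),
                        n = sample(3:90, config$n_phosphosites, replace = TRUE),
                        stringsAsFactors = FALSE)
  list(transcriptome = transcriptome, tf_activity = activity, phospho = phospho,
       kinase_map = truth$kinase_map, regulons = truth$regulons)
}

#' Simulate a two-group expression matrix with an optional planted set
#'
#' Emulates the anchor-high versus anchor-low proteome comparison used for
#' permutation GSEA: background genes are standard normal in both groups;
#' members of `planted_genes` are shifted by `shift` in group A.
#'
#' @param n_genes gene count; @param n_a,n_b group sizes.
#' @param planted_genes character vector of gene names to shift (may be empty).
#' @param shift mean shift of planted genes in group A.
#' @param noise_sd residual sd.
#' @param seed RNG seed.
#' @return list with `matrix` (`quant_matrix`, group labels set), `groups`.
#' @export
generate_two_group_matrix <- function(n_genes = 1000, n_a = 20, n_b = 20,
                                      planted_genes = character(0), shift = 1,
                                      noise_sd = 1, seed = 1) {
  set.seed(as.integer(seed))
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  vals <- matrix(stats::rnorm(n_genes * (n_a + n_b), 0, noise_sd),
                 nrow = n_genes, dimnames = list(paste0(genes, "X"), samples))
  ix <- match(intersect(planted_genes, genes), genes)
  if (length(ix)) vals[ix, seq_len(n_a)] <- vals[ix, seq_len(n_a)] + shift
  groups <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)
  m <- quant_matrix(vals, gene_symbol = genes, layer = "tissue",
                    scale = "log2", group = groups)
  list(matrix = m, groups = groups)
}

#' Simulate all layers at once
#'
#' @param config a [generator_config()].
#' @return list with every layer plus the `truth` object.
#' @export
simulate_layers <- function(config = generator_config()) {
  truth <- generator_truth(config)
  plasma <- generate_stage_profiles(config, truth)
  silac <- generate_silac(config, truth)
  tissue <- generate_tissue_cohort(config, truth)
  tp <- generate_transcriptome_and_phospho(config, truth, tissue)
  list(config = config, truth = truth, plasma = plasma, silac = silac,
       tissue = tissue, transcriptome = tp$transcriptome,
       tf_activity = tp$tf_activity, phospho = tp$phospho,
       kinase_map = tp$kinase_map, regulons = tp$regulons)
}

#' Linear-scale export of a z-profile matrix
#'
#' Maps z-profiles to a plausible linear intensity scale (2^z * 1e6) for
#' exercising linear-scale I/O; the downstream clustering re-z-scores rows,
#' so the transform is analysis-neutral.
#' @param x a log2/z-scale `quant_matrix`.
#' @return a linear-scale `quant_matrix`.
#' @export
as_linear_lfq <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  x$values <- 2^x$values * 1e6
  x$scale <- "linear"
  x
}

#' Write all simulated layers to disk
#'
#' Emits every layer in the package's text formats (quant matrices, SILAC
#' ratio TSV with an orientation header row, regulon and kinase-substrate
#' edge tables, phosphosite TSV, module/random gene sets as GMT) plus
#' `truth.json` for downstream recovery checks.
#'
#' @param sim result of [simulate_layers()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_layers <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_quant_matrix(sim$plasma, p("plasma.tsv"))
  write_quant_matrix(sim$tissue, p("tissue.tsv"))
  write_quant_matrix(sim$transcriptome, p("transcriptome.tsv"))
  utils::write.table(
    data.frame(sample = names(sim$tissue$stage), stage = sim$tissue$stage),
    p("tissue_samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_silac(sim$silac, p("silac.tsv"))
  utils::write.table(sim$phospho, p("phospho.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ks <- data.frame(kinase = rep(names(sim$kinase_map), lengths(sim$kinase_map)),
                   site_id = unlist(sim$kinase_map, use.names = FALSE))
  utils::write.table(ks, p("kinase_substrates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reg <- data.frame(tf = rep(names(sim$regulons), lengths(sim$regulons)),
                    target = unlist(sim$regulons, use.names = FALSE),
                    is_predicted = 0L)
  utils::write.table(reg, p("tf_targets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  set.seed(child_seed(sim$config$seed, 5L))
  sets <- c(list(list(name = "PLANTED_MODULE", description = "synthetic",
                      members = sim$truth$planted_module)),
            lapply(1:10, function(i) list(
              name = sprintf("RANDOM_SET_%02d", i), description = "synthetic",
              members = sample(sim$truth$tissue_genes, 30))))
  write_gmt(sets, p("sets.gmt"))
  tr <- sim$truth
  jsonlite::write_json(list(
    planted_module = tr$planted_module,
    plasma_cluster = as.list(tr$plasma_cluster),
    tissue_cluster = as.list(tr$tissue_cluster),
    secretome_effect = as.list(tr$secretome_effect[tr$secretome_effect != 0]),
    active_tfs = tr$active_tfs, active_kinases = tr$active_kinases,
    seed = tr$seed), p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(stats::setNames(
    file.path(outdir, c("plasma.tsv", "tissue.tsv", "transcriptome.tsv",
                        "silac.tsv", "phospho.tsv", "kinase_substrates.tsv",
                        "tf_targets.tsv", "sets.gmt", "truth.json")),
    c("plasma", "tissue", "transcriptome", "silac", "phospho",
      "kinase_substrates", "tf_targets", "sets", "truth")))
}
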