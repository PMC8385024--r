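#' Default pipeline configuration
#'
#' All analysis defaults in one list: distance threshold 1.578 (the
#' published cut for user-supplied trees; `NULL` means calibrate to the
#' simulated cluster count), average linkage, sample sd (ddof 1),
#' quantifiability at 3 of 6 replicates, 1.5-fold change at p < 0.05 for
#' differential secretion, integration FDR 0.02, GSEA at 1000 permutations
#' and FDR 0.25, MMP2 anchor, ssGSEA exponent 0.25, and 5 minimum KSEA
#' substrates.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 7L,
    simulate = list(enabled = TRUE),
    clustering = list(threshold = NULL, linkage = "average", ddof = 1),
    secretome = list(min_obs = 3, fc = 1.5, alpha = 0.05, use_adjusted = FALSE),
    integration = list(fdr = 0.02),
    gsea = list(n_perm = 1000, fdr = 0.25, weight_p = 1),
    activity = list(anchor = "MMP2", alpha = 0.25, min_substrates = 5))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills every default, reports
#' all out-of-range values at once, and rejects unknown keys.
#'
#' @param config YAML path or list (empty/`NULL` means all defaults).
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "seed") { def$seed <- config$seed; next }
    if (sec == "simulate" && !is.list(config$simulate)) {
      def$simulate$enabled <- isTRUE(config$simulate); next
    }
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (sec == "simulate")
      bad <- setdiff(bad, names(formals(generator_config)))
    if (length(bad))
      stop(sprintf("unknown config keys in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    def[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  cl <- def$clustering
  chk(is.null(cl$threshold) || cl$threshold >= 0, "clustering$threshold must be >= 0")
  chk(cl$linkage %in% c("average", "complete", "ward"), "unknown clustering$linkage")
  chk(cl$ddof %in% c(0, 1), "clustering$ddof must be 0 or 1")
  se <- def$secretome
  chk(se$min_obs >= 2, "secretome$min_obs must be >= 2")
  chk(se$fc >= 1, "secretome$fc must be >= 1")
  chk(se$alpha > 0 && se$alpha <= 1, "secretome$alpha must be in (0,1]")
  chk(def$integration$fdr > 0 && def$integration$fdr <= 1,
      "integration$fdr must be in (0,1]")
  chk(def$gsea$n_perm >= 100, "gsea$n_perm must be >= 100")
  chk(def$gsea$fdr > 0 && def$gsea$fdr <= 1, "gsea$fdr must be in (0,1]")
  chk(def$activity$alpha >= 0, "activity$alpha must be >= 0")
  chk(def$activity$min_substrates >= 1, "activity$min_substrates must be >= 1")
  chk(is.numeric(def$seed) && length(def$seed) == 1, "seed must be a single integer")
  if (length(errs)) stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  def
}

run_stage <- function(name, outdir, cache, summary_env, fun) {
  cache_file <- file.path(outdir, sprintf("stage_%s.rds", name))
  t0 <- proc.time()[["elapsed"]]
  if (cache && file.exists(cache_file)) {
    out <- readRDS(cache_file)
    summary_env$stages[[name]] <- list(cached = TRUE, seconds = 0)
    return(out)
  }
  warns <- character(0)
  out <- withCallingHandlers(fun(), warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  saveRDS(out, cache_file)
  summary_env$stages[[name]] <- list(
    cached = FALSE, seconds = round(proc.time()[["elapsed"]] - t0, 2),
    warnings = warns)
  out
}

#' Run the full integrative analysis on simulated layers
#'
#' Stages, in dependency order: simulate all layers; z-score and cluster
#' the plasma stage profiles; orient, aggregate, flag and categorize the
#' SILAC secretome; collapse, z-score and cluster the tissue cohort;
#' Fisher association of plasma and tissue clusters with secretome
#' categories plus the three-way signature intersection; annotation
#' enrichment of the down-regulated secretome; permutation GSEA of the
#' anchor-high/low tissue split; regulon activity and KSEA. Each stage's
#' result is cached in `outdir` (`stage_*.rds`), so deleting one cache
#' file and re-running recomputes only that stage. All randomness flows
#' from `config$seed`; a fixed seed gives identical outputs.
#'
#' @param config a list or YAML path accepted by [validate_config()].
#' @param outdir output directory for stage outputs, TSV exports and
#'   `run_summary.json`.
#' @param cache reuse cached stage results when present (default `TRUE`).
#' @return invisibly, a list with every stage result plus the run summary.
#' @export
run_all <- function(config = NULL, outdir, cache = TRUE) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sm <- new.env(); sm$stages <- list()
  t_start <- proc.time()[["elapsed"]]
  if (!isTRUE(cfg$simulate$enabled))
    stop("this driver runs on simulated layers; set simulate$enabled = TRUE")
  gen_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
  gen_args$seed <- as.integer(cfg$seed)
  gcfg <- do.call(generator_config, gen_args)

  sim <- run_stage("simulate", outdir, cache, sm, function() {
    s <- simulate_layers(gcfg); write_layers(s, file.path(outdir, "layers")); s
  })

  plasma_cl <- run_stage("plasma_clusters", outdir, cache, sm, function() {
    prof <- zscore_profiles(sim$plasma, ddof = cfg$clustering$ddof)
    dend <- hierarchical_cluster(prof, linkage = cfg$clustering$linkage)
    thr <- if (is.null(cfg$clustering$threshold))
      threshold_for_k(dend, gcfg$n_plasma_clusters) else cfg$clustering$threshold
    asn <- cut_at_threshold(dend, thr)
    list(profiles = prof, assignment = asn,
         summary = cluster_profiles_summary(asn, prof),
         gene_of = stats::setNames(prof$gene_symbol, rownames(prof$z)))
  })

  secretome <- run_stage("secretome", outdir, cache, sm, function() {
    st <- aggregate_replicates(orient_ratios(sim$silac), min_obs = cfg$secretome$min_obs)
    st <- call_deps(st, cfg$secretome$fc, cfg$secretome$alpha,
                    cfg$secretome$use_adjusted)
    categorize(st, cfg$secretome$fc)
  })

  tissue_cl <- run_stage("tissue_clusters", outdir, cache, sm, function() {
    prof <- zscore_profiles(collapse_to_stage_means(sim$tissue),
                            ddof = cfg$clustering$ddof)
    dend <- hierarchical_cluster(prof, linkage = cfg$clustering$linkage)
    thr <- if (is.null(cfg$clustering$threshold))
      threshold_for_k(dend, gcfg$n_tissue_clusters) else cfg$clustering$threshold
    asn <- cut_at_threshold(dend, thr)
    list(profiles = prof, assignment = asn,
         summary = cluster_profiles_summary(asn, prof),
         gene_of = stats::setNames(prof$gene_symbol, rownames(prof$z)))
  })

  integration <- run_stage("integration", outdir, cache, sm, function() {
    cat_by_gene <- stats::setNames(secretome$category, secretome$gene)
    cat_by_gene <- cat_by_gene[!is.na(cat_by_gene)]
    cl_by_gene <- function(cl) stats::setNames(
      as.integer(cl$assignment$labels), cl$gene_of[names(cl$assignment$labels)])
    plasma_assoc <- association_matrix(cl_by_gene(plasma_cl), cat_by_gene,
                                       fdr = cfg$integration$fdr)
    tissue_assoc <- association_matrix(cl_by_gene(tissue_cl), cat_by_gene,
                                       fdr = cfg$integration$fdr)
    top_pair <- function(am) {
      score <- ifelse(is.na(am$ef) | !am$significant, -Inf, am$ef)
      if (all(!is.finite(score))) score <- ifelse(is.na(am$ef), -Inf, am$ef)
      am[which.max(score), ]
    }
    tp_p <- top_pair(plasma_assoc); tp_t <- top_pair(tissue_assoc)
    pg <- cl_by_gene(plasma_cl); tg <- cl_by_gene(tissue_cl)
    sig <- intersect_signature(list(
      secretome_cat = names(cat_by_gene)[cat_by_gene == tp_p$category],
      plasma_cluster = names(pg)[pg == tp_p$cluster],
      tissue_cluster = names(tg)[tg == tp_t$cluster]))
    list(plasma_assoc = plasma_assoc, tissue_assoc = tissue_assoc,
         top_plasma = tp_p, top_tissue = tp_t, signature = sig)
  })

  enrichment <- run_stage("enrichment", outdir, cache, sm, function() {
    sets <- read_gmt(file.path(outdir, "layers", "sets.gmt"))
    quant <- secretome[secretome$quantifiable, ]
    fisher <- fisher_annotation_enrichment(
      quant$gene[quant$dep_flag == "down"], quant$gene, sets,
      fdr = cfg$integration$fdr)
    split <- split_by_median(sim$tissue, cfg$activity$anchor)
    groups <- stats::setNames(
      ifelse(colnames(sim$tissue$values) %in% split$high, "high", "low"),
      colnames(sim$tissue$values))
    gsea <- gsea_permutation(sim$tissue, groups, sets,
                             n_perm = cfg$gsea$n_perm,
                             seed = child_seed(cfg$seed, 6L),
                             weight_p = cfg$gsea$weight_p, fdr = cfg$gsea$fdr)
    list(fisher = fisher, gsea = gsea, split = split)
  })

  activity <- run_stage("activity", outdir, cache, sm, function() {
    anchor_vec <- enrichment$split$values
    tf <- regulon_activity(sim$transcriptome, sim$regulons,
                           alpha = cfg$activity$alpha, anchor_vector = anchor_vec)
    ks <- ksea(sim$phospho, sim$kinase_map,
               min_substrates = cfg$activity$min_substrates)
    corr <- spearman_screen(sim$tissue, anchor_vec)
    list(tf = tf, ksea = ks, anchor_screen = corr)
  })

  wt <- function(df, f) utils::write.table(df, file.path(outdir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(data.frame(accession = names(plasma_cl$assignment$labels),
                gene = plasma_cl$gene_of[names(plasma_cl$assignment$labels)],
                cluster = plasma_cl$assignment$labels), "plasma_clusters.tsv")
  wt(data.frame(accession = names(tissue_cl$assignment$labels),
                gene = tissue_cl$gene_of[names(tissue_cl$assignment$labels)],
                cluster = tissue_cl$assignment$labels), "tissue_clusters.tsv")
  wt(secretome, "secretome_stats.tsv")
  wt(integration$plasma_assoc, "plasma_association.tsv")
  wt(integration$tissue_assoc, "tissue_association.tsv")
  wt(data.frame(gene = integration$signature$signature), "signature.tsv")
  wt(enrichment$fisher, "annotation_enrichment.tsv")
  wt(enrichment$gsea[setdiff(names(enrichment$gsea), "leading_edge")], "gsea.tsv")
  wt(activity$ksea, "ksea.tsv")
  wt(activity$tf$correlation, "tf_activity_correlation.tsv")

  summary <- list(
    version = as.character(utils::packageVersion("protlayers")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "simulate")],
    counts = list(
      plasma_proteins = nrow(sim$plasma$values),
      plasma_clustered = length(plasma_cl$assignment$labels),
      plasma_k = plasma_cl$assignment$k,
      secretome_quantifiable = sum(secretome$quantifiable),
      deps_down = sum(secretome$dep_flag == "down"),
      deps_up = sum(secretome$dep_flag == "up"),
      tissue_clustered = length(tissue_cl$assignment$labels),
      tissue_k = tissue_cl$assignment$k,
      signature_size = length(integration$signature$signature)),
    stages = sm$stages,
    seconds_total = round(proc.time()[["elapsed"]] - t_start, 2))
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, sim = sim, plasma = plasma_cl,
                 secretome = secretome, tissue = tissue_cl,
                 integration = integration, enrichment = enrichment,
                 activity = activity, summary = summary))
}
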