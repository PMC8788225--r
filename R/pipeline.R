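# End-to-end orchestration: metrics -> family profiling -> clustering ->
# expression similarity -> evolutionary/expression pairing, from a single
# validated configuration, with seeded determinism and graceful
# degradation when optional inputs are absent.

#' Build and validate a pipeline run configuration
#'
#' All referenced paths must exist at validation time. Optional inputs
#' (orders, SNPs, tracks, expression map) may be NULL: the corresponding
#' metrics are emitted as missing, never fabricated.
#'
#' @param orthology,tree paths to the orthology TSV and newick tree
#'   (required).
#' @param catalog path to the gene catalog TSV (required).
#' @param orders,snps,models,phc_track,wga_track,expression_map optional
#'   input paths.
#' @param grid_rows,grid_cols expression map grid dimensions.
#' @param focal_species optional focal species for site metrics.
#' @param stat `"mean"` or `"median"` family aggregate.
#' @param n_perm permutations for the significance tests.
#' @param n_per_scale bootstrap replicates per scale per combination.
#' @param distances,linkages clustering method sets.
#' @param resolution expression resolution(s) to compute.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return validated `run_config` list.
#' @export
run_config <- function(orthology, tree, catalog, orders = NULL, snps = NULL,
                       models = NULL, phc_track = NULL, wga_track = NULL,
                       expression_map = NULL, grid_rows = 30L, grid_cols = 30L,
                       focal_species = NULL, stat = "median",
                       n_perm = 1000L, n_per_scale = 100L,
                       distances = CLUSTER_DISTANCES,
                       linkages = CLUSTER_LINKAGES,
                       resolution = "cell", seed = 1L, out_dir = "evoprofiler_run") {
  cfg <- list(orthology = orthology, tree = tree, catalog = catalog,
              orders = orders, snps = snps, models = models,
              phc_track = phc_track, wga_track = wga_track,
              expression_map = expression_map, grid_rows = grid_rows,
              grid_cols = grid_cols, focal_species = focal_species,
              stat = stat, n_perm = n_perm, n_per_scale = n_per_scale,
              distances = distances, linkages = linkages,
              resolution = resolution, seed = as.integer(seed),
              out_dir = out_dir)
  for (f in c("orthology", "tree", "catalog", "orders", "snps", "models",
              "phc_track", "wga_track", "expression_map")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config path for '", f, "' does not exist: ", p, call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full profiling pipeline
#'
#' Stages run in dependency order: OG metrics (orthology-, turnover-,
#' divergence- and site-based), family profiles with significance,
#' profile clustering with bootstrap support and the family similarity
#' matrix, expression co-occurrence (when a map is supplied), and the
#' evolutionary/expression pairing. All tabular outputs are written as
#' TSV under `config$out_dir`; a run log records seeds and counts.
#'
#' @param config `run_config`.
#' @param alignments optional named list of codon alignments per OG.
#' @return list with all output tables.
#' @export
run_pipeline <- function(config, alignments = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("seed", config$seed),
                 paste("run started", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  tree <- stage("read_tree", read_species_tree(config$tree))
  species <- tree$phylo$tip.label
  orth <- stage("read_orthology", read_orthology(config$orthology, species))
  catalog <- stage("read_catalog", read_gene_catalog(config$catalog))
  orders <- if (!is.null(config$orders))
    stage("read_orders", read_gene_orders(config$orders)) else NULL

  ogm <- stage("og_metrics", og_metrics(orth, tree, orders = orders))
  ev <- stage("turnover", branch_events(orth, tree))
  ogm <- merge(ogm, turnover_proportions(ev), by = "og_id", all.x = TRUE)
  if (!is.null(alignments)) {
    ogm <- merge(ogm, stage("divergence", divergence_metrics(alignments)),
                 by = "og_id", all.x = TRUE)
  }
  snps <- if (!is.null(config$snps))
    stage("read_snps", read_snp_table(config$snps)) else NULL
  models <- if (!is.null(config$models))
    stage("read_models", read_gene_models(config$models)) else NULL
  phc <- if (!is.null(config$phc_track))
    stage("read_phc", read_track(config$phc_track, range = c(0, 1))) else NULL
  wga <- if (!is.null(config$wga_track))
    stage("read_wga", read_track(config$wga_track,
                                 range = c(0, length(species)))) else NULL
  if (!is.null(snps) || (!is.null(models) && (!is.null(phc) || !is.null(wga)))) {
    sm <- stage("site_metrics",
                site_metrics(orth, snps = snps, models = models,
                             wga_track = wga, phc_track = phc,
                             focal_species = config$focal_species))
    ogm <- merge(ogm, sm, by = "og_id", all.x = TRUE)
  }
  ogm <- og_metric_table(ogm, n_species = length(species))
  write_metric_table(ogm, file.path(config$out_dir, "og_metrics.tsv"))
  log_lines <- c(log_lines, paste("og_metrics", nrow(ogm), "OGs"))

  prof <- stage("family_profile",
                family_profile_table(ogm, catalog, orth, stat = config$stat,
                                     n_perm = config$n_perm,
                                     seed = config$seed))
  write_tsv(as.data.frame(prof), file.path(config$out_dir, "family_profile.tsv"))

  pm <- profile_matrix(prof, value = config$stat)
  keep <- colSums(!is.na(pm)) == nrow(pm)
  dropped <- colnames(pm)[!keep]
  if (length(dropped) > 0)
    log_lines <- c(log_lines,
                   paste("clustering dropped incomplete metric(s):",
                         paste(dropped, collapse = ",")))
  clust <- NULL
  if (sum(keep) >= 3 && nrow(pm) >= 3) {
    scaled <- scale_profile_matrix(pm[, keep, drop = FALSE])
    clust <- stage("clustering",
                   cluster_family_profiles(scaled,
                                           distances = config$distances,
                                           linkages = config$linkages,
                                           n_per_scale = config$n_per_scale,
                                           seed = config$seed))
    write_tsv(as.data.frame(as.matrix(clust$similarity)),
              file.path(config$out_dir, "family_similarity.tsv"))
    headline <- clust$combinations[["pearson.average"]] %||%
      clust$combinations[[1]]
    write_dendrogram_newick(headline,
                            file.path(config$out_dir, "dendrogram.nwk"))
    pca <- pca_profiles(scaled)
    write_tsv(data.frame(component = seq_along(pca$variance_explained),
                         variance_explained = pca$variance_explained),
              file.path(config$out_dir, "pca_variance.tsv"))
    log_lines <- c(log_lines,
                   paste("bootstrap replicates", clust$n_replicates_total))
  }

  coexpr <- NULL; pairing <- NULL
  if (!is.null(config$expression_map)) {
    emap <- stage("read_map",
                  read_expression_map(config$expression_map,
                                      config$grid_rows, config$grid_cols))
    coexpr <- stage("coexpression",
                    family_cooccurrence_table(emap, catalog,
                                              resolution = config$resolution,
                                              n_perm = config$n_perm,
                                              seed = config$seed))
    write_tsv(as.data.frame(coexpr), file.path(config$out_dir, "coexpression.tsv"))
    export_similarity_graph(coexpr,
                            file.path(config$out_dir, "coexpression.dot"))
    if (!is.null(clust)) {
      pairing <- evo_expr_pairing(clust$similarity, coexpr)
      write_tsv(pairing, file.path(config$out_dir, "evo_expr_pairing.tsv"))
    }
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(og_metrics = ogm, profile = prof, clustering = clust,
                 coexpression = coexpr, pairing = pairing,
                 log = log_lines))
}
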