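#' Pipeline configuration
#'
#' One list of input paths, thresholds, sampling controls and flags drives
#' [run_pipeline()]. Thresholds default to the analysis conventions: Ct
#' detection cutoff 30, missingness cutoff 0.20, haemolysis delta-Cq cutoffs
#' 5/7, pfp (FDR) cutoff 0.05, interactome confidence 0.4, at least 2
#' supporting target sources, coherence significance z < -1.65.
#'
#' @param ct_csv,metadata_tsv,interactome_tsv,rank_tables_tsv,gmt,attributes_tsv,gene_list
#'   input file paths (network/target/enrichment stages are skipped when their
#'   inputs are `NULL`)
#' @param out_dir output directory (created if missing)
#' @param ct_threshold,max_missing_fraction,possible_threshold,high_threshold,fdr,min_score,min_sources,z_cutoff
#'   thresholds
#' @param n_sv `"auto"` or fixed surrogate-variable count
#' @param n_perm rank-product permutations
#' @param n_random null draws for enrichment/coherence
#' @param max_comparisons cap on rank-product case-control pairings
#' @param n_components Bayesian-PCA latent dimension
#' @param seed master seed; stage seeds are derived from it
#' @param degree_matched_null use degree-binned null sampling
#' @param full_network_centrality compute centralities on the full network
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(ct_csv, metadata_tsv, out_dir,
                            interactome_tsv = NULL, rank_tables_tsv = NULL,
                            gmt = NULL, attributes_tsv = NULL, gene_list = NULL,
                            ct_threshold = 30, max_missing_fraction = 0.20,
                            possible_threshold = 5, high_threshold = 7,
                            fdr = 0.05, min_score = 0.4, min_sources = 2,
                            z_cutoff = -1.65, n_sv = "auto", n_perm = 1000,
                            n_random = 1000, max_comparisons = 50,
                            n_components = 5, seed = 1,
                            degree_matched_null = FALSE,
                            full_network_centrality = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$ct_threshold > 0, cfg$fdr > 0, cfg$fdr < 1,
            cfg$max_missing_fraction >= 0, cfg$max_missing_fraction <= 1,
            cfg$min_score >= 0, cfg$min_score < 1, cfg$min_sources >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with fields matching [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: QC (detection filter, haemolysis exclusion, missingness filter,
#' quantile normalization) -> Bayesian-PCA imputation -> surrogate-variable
#' adjustment (protecting case status, removing surrogate variables plus the
#' intervention arm) -> rank-product differential expression for the case
#' contrast and the vitamin-D contrast -> signature intersection -> disease
#' module on the interactome (mapping, PPI enrichment, LCC, coherence,
#' centrality) -> consensus target aggregation and projection onto the module
#' -> annotation-set and attribute enrichment. All artifacts are written under
#' `config$out_dir`; a machine-readable run report summarizes per-stage
#' counts and seeds.
#'
#' @param config a [pipeline_config()] (or path to a YAML file)
#' @return the run report, invisibly (also written as `run_report.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  report <- list(seed = config$seed, stages = list())

  # --- QC / normalization -------------------------------------------------
  meta <- read_metadata_tsv(config$metadata_tsv)
  ct <- read_ct_csv(config$ct_csv, metadata = meta)
  qc <- qc_pipeline(ct, ct_threshold = config$ct_threshold,
                    max_missing_fraction = config$max_missing_fraction,
                    possible_threshold = config$possible_threshold,
                    high_threshold = config$high_threshold)
  jsonlite::write_json(
    list(hemolysis = qc$hemolysis, dropped_features = qc$dropped_features,
         excluded_samples = qc$excluded_samples, counts = as.list(qc$counts)),
    art("qc_report.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report$stages$qc <- as.list(qc$counts)

  # --- imputation ---------------------------------------------------------
  imp <- impute_bpca(qc$ct, n_components = config$n_components)
  write_ct_csv(imp, art("processed_ct.csv"))
  report$stages$imputation <- list(
    n_imputed = sum(attr(imp, "imputed_mask")),
    converged = attr(imp, "converged"))

  # --- surrogate-variable adjustment --------------------------------------
  md <- imp$metadata
  expr <- -imp$values                    # expression scale: higher = more abundant
  # both phenotype contrasts are known covariates: protect them (and the
  # intervention arm) so surrogate variables cannot absorb their effects;
  # only the arm and the surrogate variables are subtracted
  arm <- if ("arm" %in% names(md)) md[, "arm", drop = FALSE] else NULL
  vitd <- if ("vitd" %in% names(md)) md[, "vitd", drop = FALSE] else NULL
  protect <- if (is.null(arm) && is.null(vitd)) NULL else
    do.call(cbind, Filter(Negate(is.null), list(arm, vitd)))
  svs <- estimate_surrogate_variables(expr, primary = md$group,
                                      protect = protect, n_sv = config$n_sv,
                                      seed = config$seed + 1L)
  adj <- remove_unwanted_variation(expr, svs, primary = md$group,
                                   nuisance = arm, keep = vitd)
  report$stages$sva <- list(n_sv = svs$n_sv)

  # --- differential expression, two contrasts -----------------------------
  de_pe <- rank_product_test(adj, md$group, case = "case",
                             n_perm = config$n_perm,
                             max_comparisons = config$max_comparisons,
                             seed = config$seed + 2L)
  sig_pe <- significant_features(de_pe, fdr = config$fdr)
  de_vd <- rank_product_test(adj, md$vitd, case = "insufficient",
                             n_perm = config$n_perm,
                             max_comparisons = config$max_comparisons,
                             seed = config$seed + 3L)
  sig_vd <- significant_features(de_vd, fdr = config$fdr)
  inter <- intersect_signatures(sig_pe, sig_vd)
  write_signature_tsv(sig_pe, art("signature_pe.tsv"))
  write_signature_tsv(sig_vd, art("signature_vitd.tsv"))
  write_signature_tsv(inter, art("signature_intersection.tsv"))
  report$stages$de <- list(n_de_case = nrow(sig_pe), n_de_vitd = nrow(sig_vd),
                           n_intersection = nrow(inter),
                           n_perm = config$n_perm,
                           n_comparisons = de_pe$n_comparisons)

  # --- disease module -----------------------------------------------------
  net <- module <- NULL
  null_model <- if (config$degree_matched_null) "degree" else "uniform"
  if (!is.null(config$interactome_tsv) && !is.null(config$gene_list)) {
    net <- read_interactome(config$interactome_tsv, min_score = config$min_score)
    genes <- read_gene_list(config$gene_list)
    module <- extract_lcc(net, map_gene_set(net, genes))
    enr <- ppi_enrichment(net, module$mapped_genes, n_random = config$n_random,
                          seed = config$seed + 4L, null_model = null_model)
    coh <- module_coherence(net, module$mapped_genes,
                            n_random = config$n_random,
                            seed = config$seed + 5L,
                            z_cutoff = config$z_cutoff,
                            null_model = null_model)
    scope <- if (config$full_network_centrality) "network" else "module"
    cent <- node_centrality(net, module$mapped_genes, scope = scope)
    write_module_graphml(net, module, art("module.graphml"))
    write_components_tsv(module, art("components.tsv"))
    jsonlite::write_json(list(enrichment = unclass(enr),
                              coherence = unclass(coh)),
                         art("module_stats.json"), auto_unbox = TRUE, digits = NA)
    report$stages$module <- list(
      n_query = length(unique(toupper(module$query_genes))),
      n_mapped = length(module$mapped_genes),
      n_lcc = length(module$lcc_members),
      lcc_fraction = length(module$lcc_members) / length(module$mapped_genes),
      observed_edges = enr$observed_edges, expected_edges = enr$expected_edges,
      enrichment_p = enr$empirical_p, coherence_z = coh$z_score,
      coherence_significant = coh$significant)
  }

  # --- miRNA targets ------------------------------------------------------
  if (!is.null(config$rank_tables_tsv) && !is.null(module)) {
    tables <- read_rank_tables_tsv(config$rank_tables_tsv)
    targets <- aggregate_targets(tables, min_sources = config$min_sources)
    sig_for_map <- data.frame(feature = inter$feature,
                              direction = inter$direction_a,
                              stringsAsFactors = FALSE)
    mt <- map_targets_to_module(targets, module, sig_for_map)
    write_target_table_tsv(targets, art("consensus_targets.tsv"))
    write_module_targets_tsv(mt, art("module_targets.tsv"))
    tg <- unique(mt$hits$target)
    sub <- if (length(tg)) target_subnetwork(net, module, tg) else NULL
    if (!is.null(sub) && length(sub$members))
      igraph::write_graph(sub$graph, art("target_subnetwork.graphml"),
                          format = "graphml")
    report$stages$targets <- list(
      n_consensus_pairs = nrow(targets),
      total = unname(mt$totals["total"]), unique = unname(mt$totals["unique"]),
      lcc_total = unname(mt$totals["lcc_total"]),
      lcc_unique = unname(mt$totals["lcc_unique"]),
      subnetwork_size = if (is.null(sub)) 0L else length(sub$members),
      top_hub = if (!is.null(sub) && length(sub$hubs)) sub$hubs[1] else NA)
  }

  # --- enrichment ---------------------------------------------------------
  if (!is.null(config$gmt) && !is.null(module)) {
    sets <- read_gmt(config$gmt)
    universe <- igraph::V(net)$name
    enr_tab <- hypergeometric_enrichment(module$lcc_members, sets, universe,
                                         fdr_cutoff = config$fdr)
    write_enrichment_tsv(enr_tab, art("enrichment.tsv"))
    report$stages$enrichment <- list(
      n_sets_tested = nrow(enr_tab),
      n_significant = sum(enr_tab$significant),
      top_set = enr_tab$set_id[1])
  }
  if (!is.null(config$attributes_tsv) && !is.null(module)) {
    attrib <- utils::read.delim(config$attributes_tsv, stringsAsFactors = FALSE)
    ae <- attribute_enrichment(module$mapped_genes, attrib,
                               universe = igraph::V(net)$name)
    report$stages$attribute <- ae
  }

  report$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, art("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Generate a complete set of synthetic pipeline inputs on disk
#'
#' Writes every input [run_pipeline()] consumes -- Ct matrix CSV, metadata
#' TSV, STRING-dialect interactome TSV, per-source rank-table TSV, GMT
#' collection, binary attribute TSV, gene-list text -- plus the ground truth
#' as JSON, all generated with the requested configuration. The planted
#' interactome module doubles as the "disease gene signature" (with a few
#' extra scattered genes and unmappable symbols, so mapping and LCC
#' extraction are exercised); the shared DE miRNAs receive planted targets
#' inside the module.
#'
#' @param out_dir output directory
#' @param config a [synthetic_config()]
#' @param seed master seed
#' @param n_nodes,background_p,module_size,module_p interactome parameters
#' @param n_extra_genes scattered non-module genes added to the gene list
#' @param n_absent_symbols unmappable symbols added to the gene list
#' @param targets_per_mirna planted targets per shared DE miRNA
#' @param rank_noise jitter of planted target ranks
#' @return list: `paths` (named input paths), `truth`
#' @export
simulate_study_inputs <- function(out_dir, config = synthetic_config(), seed = 1,
                                  n_nodes = 500, background_p = 0.01,
                                  module_size = 60, module_p = 0.25,
                                  n_extra_genes = 20, n_absent_symbols = 4,
                                  targets_per_mirna = 8, rank_noise = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ds <- generate_ct_dataset(config, seed = seed)
  ppi <- generate_ppi(n_nodes, background_p, module_size, module_p,
                      seed = seed + 1L)
  withr::with_seed(seed + 2L, {
    all_nodes <- igraph::V(ppi$graph)$name
    extra <- sample(setdiff(all_nodes, ppi$truth$module_nodes), n_extra_genes)
    absent <- sprintf("FAKE%02d", seq_len(n_absent_symbols))
    gene_list <- sample(c(ppi$truth$module_nodes, extra, absent))
    shared <- c(ds$truth$shared_up_ids, ds$truth$shared_down_ids)
    planted_map <- stats::setNames(lapply(shared, function(m)
      sample(ppi$truth$module_nodes, targets_per_mirna)), shared)
    # placenta-style binary attribute: enriched inside the module
    flag <- ifelse(all_nodes %in% ppi$truth$module_nodes,
                   stats::runif(n_nodes) < 0.8, stats::runif(n_nodes) < 0.3)
    attrib <- data.frame(gene = all_nodes, expressed_in_placenta = as.integer(flag))
  })
  tables <- generate_target_tables(
    mirna_ids = feature_ids(ds$ct), gene_ids = igraph::V(ppi$graph)$name,
    planted_map = planted_map, rank_noise = rank_noise, seed = seed + 3L)
  sets <- generate_annotation_sets(igraph::V(ppi$graph)$name,
                                   ppi$truth$module_nodes, seed = seed + 4L)
  write_ct_csv(ds$ct, p("ct_matrix.csv"))
  write_metadata_tsv(ds$ct$metadata, p("metadata.tsv"))
  write_string_tsv(ppi$graph, p("interactome.tsv"))
  write_rank_tables_tsv(tables, p("rank_tables.tsv"))
  write_gmt(sets, p("annotation.gmt"))
  utils::write.table(attrib, p("attributes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(gene_list, p("gene_list.txt"))
  truth <- c(ds$truth, list(planted_module_genes = ppi$truth$module_nodes,
                            planted_target_map = planted_map,
                            gene_list_absent = absent))
  write_truth_json(truth[setdiff(names(truth),
                                 c("factor_scores", "factor_loadings"))],
                   p("truth.json"))
  list(paths = list(ct_csv = p("ct_matrix.csv"), metadata_tsv = p("metadata.tsv"),
                    interactome_tsv = p("interactome.tsv"),
                    rank_tables_tsv = p("rank_tables.tsv"),
                    gmt = p("annotation.gmt"), attributes_tsv = p("attributes.tsv"),
                    gene_list = p("gene_list.txt"), truth = p("truth.json")),
       truth = truth)
}
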