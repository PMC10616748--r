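#' Synthetic study configuration
#'
#' Defaults emulate the structure of an early-pregnancy qPCR miRNA
#' case-control cohort: 754 assayed miRNAs in 157 samples (47 preeclampsia
#' cases, 110 controls), two phenotype contrasts (case status and a
#' dichotomised vitamin-D status) with a planted shared differential-expression
#' subset, hidden batch-like factors, abundance-dependent nondetects and a few
#' haemolysed samples.
#'
#' @param n_features,n_samples,n_cases cohort dimensions
#' @param n_de_up,n_de_down features planted differentially expressed in cases
#'   (up = lower Ct in cases)
#' @param n_de_shared_up,n_de_shared_down subset of the case-DE features also
#'   planted for the vitamin-D contrast (the "shared signature")
#' @param n_de_vitd_only extra features planted only for the vitamin-D contrast
#' @param effect_size_ct,vitd_effect_ct planted shifts in Cq units
#' @param n_hidden_factors,factor_sd hidden Gaussian sample factors with
#'   N(0, factor_sd) per-feature loadings (the structure surrogate-variable
#'   analysis models)
#' @param nondetect_rate plateau probability of a nondetect at high Ct; the
#'   per-cell probability rises logistically with the underlying Ct
#'   (nondetects are abundance-dependent)
#' @param hemolysis_samples number of samples with a planted haemolysis
#'   artefact (erythrocyte miR-451a released, lowering its Cq)
#' @param baseline_ct_range uniform range for per-feature baseline Cq
#' @param noise_sd per-cell Gaussian noise, Cq units
#' @return a `synthetic_config` list, validated
#' @export
synthetic_config <- function(n_features = 754, n_samples = 157, n_cases = 47,
                             n_de_up = 10, n_de_down = 21,
                             n_de_shared_up = 9, n_de_shared_down = 7,
                             n_de_vitd_only = 10,
                             effect_size_ct = 1.0, vitd_effect_ct = 1.0,
                             n_hidden_factors = 2, factor_sd = 0.5,
                             nondetect_rate = 0.6, hemolysis_samples = 3,
                             baseline_ct_range = c(22, 36), noise_sd = 1.0) {
  cfg <- as.list(environment())
  if (n_cases >= n_samples) stop("n_cases must be < n_samples")
  if (n_de_up + n_de_down + n_de_vitd_only > n_features)
    stop("planted DE counts exceed n_features")
  if (n_de_shared_up > n_de_up || n_de_shared_down > n_de_down)
    stop("shared DE counts exceed the case-DE counts")
  if (nondetect_rate < 0 || nondetect_rate > 1)
    stop("nondetect_rate must be in [0, 1]")
  if (hemolysis_samples > n_samples) stop("hemolysis_samples exceeds n_samples")
  if (length(baseline_ct_range) != 2 || diff(baseline_ct_range) < 0)
    stop("baseline_ct_range must be (low, high)")
  if (noise_sd < 0 || factor_sd < 0) stop("sd parameters must be >= 0")
  structure(cfg, class = "synthetic_config")
}

# reference haemolysis proxy assays, always present in generated matrices
.MIR23A <- "hsa-miR-23a"
.MIR451A <- "hsa-miR-451a"

#' Generate a synthetic Ct dataset with ground truth
#'
#' Ct = per-feature baseline + planted group shifts + hidden-factor
#' contributions + Gaussian noise. Nondetects are masked with probability
#' rising logistically in the underlying Ct (plateau `nondetect_rate`,
#' midpoint Ct 31, scale 2). Haemolysed samples have the miR-451a proxy
#' shifted down by 5 Cq so their delta-Cq haemolysis score exceeds 5. The
#' miR-23a and miR-451a proxy features are always present (baselines 20 and
#' 16.5) and are never planted DE.
#'
#' @param config a [synthetic_config()]
#' @param seed integer seed; all randomness is local to this call
#' @return list with `ct` (a [ct_matrix()]) and `truth` (planted feature ids,
#'   factor scores/loadings, haemolysed sample ids)
#' @export
generate_ct_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, .generate_ct_dataset(config))
}

.generate_ct_dataset <- function(cfg) {
  p <- cfg$n_features; n <- cfg$n_samples
  fids <- sprintf("hsa-miR-s%04d", seq_len(p))
  fids[1] <- .MIR23A; fids[2] <- .MIR451A
  sids <- sprintf("S%03d", seq_len(n))

  group <- rep(c("case", "control"), c(cfg$n_cases, n - cfg$n_cases))
  # vitamin-D insufficiency more prevalent among cases, as in such cohorts
  p_insuf <- ifelse(group == "case", 0.87, 0.71)
  vitd <- ifelse(stats::runif(n) < p_insuf, "insufficient", "sufficient")
  arm <- sample(c("placebo", "treatment"), n, replace = TRUE)
  meta <- data.frame(sample_id = sids, group = group, vitd = vitd, arm = arm,
                     stringsAsFactors = FALSE)

  # planted feature sets (never the proxies)
  pool <- sample(fids[-(1:2)])
  de_up <- pool[seq_len(cfg$n_de_up)]
  de_down <- pool[cfg$n_de_up + seq_len(cfg$n_de_down)]
  vitd_only <- pool[cfg$n_de_up + cfg$n_de_down + seq_len(cfg$n_de_vitd_only)]
  shared_up <- de_up[seq_len(cfg$n_de_shared_up)]
  shared_down <- de_down[seq_len(cfg$n_de_shared_down)]
  n_vo_up <- ceiling(cfg$n_de_vitd_only / 2)
  vitd_up <- c(shared_up, vitd_only[seq_len(n_vo_up)])
  vitd_down <- c(shared_down, vitd_only[setdiff(seq_len(cfg$n_de_vitd_only),
                                                seq_len(n_vo_up))])

  baseline <- stats::runif(p, cfg$baseline_ct_range[1], cfg$baseline_ct_range[2])
  names(baseline) <- fids
  baseline[.MIR23A] <- 20; baseline[.MIR451A] <- 16.5
  # planted features kept well inside the detectable range so QC retains them
  planted <- unique(c(de_up, de_down, vitd_only))
  baseline[planted] <- stats::runif(length(planted), 22, 27)

  ct <- matrix(baseline, p, n, dimnames = list(fids, sids))
  is_case <- group == "case"
  is_insuf <- vitd == "insufficient"
  ct[de_up, is_case] <- ct[de_up, is_case] - cfg$effect_size_ct
  ct[de_down, is_case] <- ct[de_down, is_case] + cfg$effect_size_ct
  ct[vitd_up, is_insuf] <- ct[vitd_up, is_insuf] - cfg$vitd_effect_ct
  ct[vitd_down, is_insuf] <- ct[vitd_down, is_insuf] + cfg$vitd_effect_ct

  scores <- loadings <- NULL
  if (cfg$n_hidden_factors > 0) {
    scores <- matrix(stats::rnorm(n * cfg$n_hidden_factors), n,
                     dimnames = list(sids, paste0("F", seq_len(cfg$n_hidden_factors))))
    loadings <- matrix(stats::rnorm(p * cfg$n_hidden_factors, sd = cfg$factor_sd), p,
                       dimnames = list(fids, colnames(scores)))
    # a batch-like shift hits a whole sample; it cancels in the within-sample
    # delta-Cq, so the two haemolysis references share one loading vector
    loadings[.MIR451A, ] <- loadings[.MIR23A, ]
    ct <- ct + loadings %*% t(scores)
  }
  if (cfg$noise_sd > 0) {
    noise <- matrix(stats::rnorm(p * n, sd = cfg$noise_sd), p, n)
    # abundant reference assays quantify precisely: tighter well noise
    ref_sd <- min(cfg$noise_sd, 0.3)
    noise[1:2, ] <- matrix(stats::rnorm(2 * n, sd = ref_sd), 2, n)
    ct <- ct + noise
  }

  hem <- character(0)
  if (cfg$hemolysis_samples > 0) {
    hem <- sample(sids, cfg$hemolysis_samples)
    ct[.MIR451A, hem] <- ct[.MIR451A, hem] - 5
  }

  # abundance-dependent nondetects: logistic in the underlying Ct
  p_nd <- cfg$nondetect_rate * stats::plogis((ct - 31) / 2)
  nd <- matrix(stats::runif(p * n) < p_nd, p, n, dimnames = dimnames(ct))

  truth <- list(
    de_up_ids = de_up, de_down_ids = de_down,
    de_vitd_up_ids = vitd_up, de_vitd_down_ids = vitd_down,
    shared_up_ids = shared_up, shared_down_ids = shared_down,
    factor_scores = scores, factor_loadings = loadings,
    hemolysed_ids = hem
  )
  list(ct = ct_matrix(ct, nondetect = nd, metadata = meta), truth = truth)
}

#' Generate a synthetic interactome with a planted dense module
#'
#' Erdos-Renyi background at `background_p` plus a planted node subset whose
#' internal pairs are connected with probability `module_p`; the planted
#' subset is forced connected (a random spanning chain is added if sampling
#' leaves it disconnected). Edge confidence scores are sampled uniformly in
#' (0.4, 1].
#'
#' @param n_nodes,background_p,module_size,module_p graph parameters;
#'   `module_p >= background_p` and `module_size >= 2` required
#' @param seed integer seed
#' @return list with `graph` (an undirected `igraph` with a `score` edge
#'   attribute) and `truth` (`module_nodes`)
#' @export
generate_ppi <- function(n_nodes, background_p, module_size, module_p, seed = 1) {
  if (module_size < 2) stop("module_size must be >= 2")
  if (module_size > n_nodes) stop("module_size exceeds n_nodes")
  if (module_p < background_p) stop("module_p must be >= background_p")
  withr::with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(n_nodes))
    g <- igraph::sample_gnp(n_nodes, background_p)
    igraph::V(g)$name <- ids
    mod <- sort(sample(ids, module_size))
    pairs <- utils::combn(mod, 2)
    take <- stats::runif(ncol(pairs)) < module_p
    if (any(take)) {
      g <- igraph::add_edges(g, as.vector(pairs[, take, drop = FALSE]))
      g <- igraph::simplify(g)
    }
    # force the planted subset connected
    sub <- igraph::induced_subgraph(g, mod)
    comp <- igraph::components(sub)
    if (comp$no > 1) {
      reps <- vapply(seq_len(comp$no),
                     function(k) sample(names(comp$membership)[comp$membership == k], 1),
                     character(1))
      chain <- as.vector(rbind(reps[-length(reps)], reps[-1]))
      g <- igraph::simplify(igraph::add_edges(g, chain))
    }
    igraph::E(g)$score <- stats::runif(igraph::ecount(g), min = 0.4 + 1e-9, max = 1)
    list(graph = g, truth = list(module_nodes = mod))
  })
}

#' Generate per-source miRNA-target rank tables
#'
#' Each planted (miRNA, gene) pair is placed in at least `min_present` of the
#' `n_sources` sources; within every source that contains it, planted pairs
#' occupy the top ranks (their order shuffled by Gaussian `rank_noise`), while
#' decoy pairs occupy strictly deeper ranks. Rank 1 is best.
#'
#' @param mirna_ids,gene_ids identifier universes
#' @param planted_map named list: miRNA id -> character vector of target genes
#' @param n_sources number of prediction sources (default 4)
#' @param rank_noise sd of the jitter applied to planted rank order
#' @param decoys_per_mirna deep-ranked decoy pairs added per miRNA per source
#' @param min_present minimum number of sources containing each planted pair
#' @param seed integer seed
#' @return list of data.frames (`source`, `mirna`, `gene`, `rank`), one per source
#' @export
generate_target_tables <- function(mirna_ids, gene_ids, planted_map,
                                   n_sources = 4, rank_noise = 1,
                                   decoys_per_mirna = 20, min_present = 2,
                                   seed = 1) {
  if (length(planted_map)) {
    if (!all(names(planted_map) %in% mirna_ids))
      stop("planted miRNAs must be drawn from mirna_ids")
    if (!all(unlist(planted_map) %in% gene_ids))
      stop("planted genes must be drawn from gene_ids")
  } else {
    warning("empty planted_map: tables contain decoys only")
  }
  stopifnot(min_present >= 1, min_present <= n_sources)
  withr::with_seed(seed, {
    src_names <- paste0("source", seq_len(n_sources))
    # which sources carry each planted pair
    carrier <- list()
    for (m in names(planted_map)) for (g in planted_map[[m]]) {
      k <- sample(seq(min_present, n_sources), 1)
      carrier[[paste(m, g, sep = "\r")]] <- sample(src_names, k)
    }
    lapply(src_names, function(src) {
      rows <- list()
      for (m in mirna_ids) {
        genes_p <- planted_map[[m]]
        genes_p <- genes_p[vapply(genes_p, function(g)
          src %in% carrier[[paste(m, g, sep = "\r")]], logical(1))]
        n_p <- length(genes_p)
        if (n_p > 0) {
          ord <- order(seq_len(n_p) + stats::rnorm(n_p, sd = rank_noise))
          genes_p <- genes_p[ord]
        }
        decoy_pool <- setdiff(gene_ids, planted_map[[m]])
        n_d <- min(decoys_per_mirna, length(decoy_pool))
        genes_d <- if (n_d > 0) sample(decoy_pool, n_d) else character(0)
        if (n_p + n_d == 0) next
        rows[[m]] <- data.frame(source = src, mirna = m,
                                gene = c(genes_p, genes_d),
                                rank = seq_len(n_p + n_d),
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
  })
}

#' Generate a GMT-style annotation collection with one enriched set
#'
#' One designated set overlaps `module_genes` at fraction `enriched_set_overlap`
#' (remaining members drawn from outside the module); the other sets are drawn
#' uniformly from the universe.
#'
#' @param gene_ids gene universe
#' @param module_genes the planted module (overlap target)
#' @param enriched_set_overlap fraction of the module included in the
#'   designated set, in `[0, 1]`
#' @param n_sets total number of sets
#' @param set_size_range (min, max) size of the uniform sets
#' @param seed integer seed
#' @return named list of character vectors with attributes `designated` (the
#'   enriched set id) and `descriptions`
#' @export
generate_annotation_sets <- function(gene_ids, module_genes,
                                     enriched_set_overlap = 0.8, n_sets = 10,
                                     set_size_range = c(10, 50), seed = 1) {
  if (enriched_set_overlap < 0 || enriched_set_overlap > 1)
    stop("enriched_set_overlap must be in [0, 1]")
  if (max(set_size_range) > length(gene_ids))
    stop("set sizes exceed the gene universe")
  module_genes <- intersect(module_genes, gene_ids)
  withr::with_seed(seed, {
    sets <- list()
    n_in <- round(enriched_set_overlap * length(module_genes))
    members <- sample(module_genes, n_in)
    pad <- max(0, round(mean(set_size_range)) - n_in)
    outside <- setdiff(gene_ids, module_genes)
    if (pad > 0) members <- c(members, sample(outside, min(pad, length(outside))))
    sets[["SET001"]] <- sort(members)
    for (i in seq_len(n_sets - 1)) {
      sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sets[[sprintf("SET%03d", i + 1)]] <- sort(sample(gene_ids, sz))
    }
    attr(sets, "designated") <- "SET001"
    attr(sets, "descriptions") <- stats::setNames(
      c("planted-module-enriched set", rep("uniform set", n_sets - 1)), names(sets))
    sets
  })
}

#' Write an interactome as a STRING-dialect TSV
#'
#' Columns `protein1`, `protein2`, `combined_score`; scores written on the
#' integer 0-1000 scale. Round-trips through [read_interactome()].
#' @param graph igraph with a `score` edge attribute in (0, 1]
#' @param path TSV path
#' @export
write_string_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                   combined_score = as.integer(round(igraph::E(graph)$score * 1000)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-source miRNA-target rank tables to one TSV
#' @param tables list of per-source data.frames from [generate_target_tables()]
#' @param path TSV path
#' @export
write_rank_tables_tsv <- function(tables, path) {
  utils::write.table(do.call(rbind, tables), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-source rank tables written by [write_rank_tables_tsv()]
#' @param path TSV path with columns source, mirna, gene, rank
#' @return list of per-source data.frames
#' @export
read_rank_tables_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "mirna", "gene", "rank")
  if (!all(need %in% names(df)))
    stop("rank table must have columns: ", paste(need, collapse = ", "))
  unname(split(df, df$source))
}

#' Write ground-truth labels as JSON
#' @param truth truth list from a generator
#' @param path JSON path
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
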