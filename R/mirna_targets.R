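#' Consensus aggregation of per-source miRNA-target ranks
#'
#' Takes the union of (miRNA, gene) pairs over all sources, keeps pairs
#' present in at least `min_sources` of them, and scores each kept pair by the
#' geometric mean of its ranks over the sources that contain it (absent
#' sources are not imputed). Within each miRNA, targets are ordered by
#' ascending score, ties broken by more supporting sources, then gene name.
#' A source supplying a `score` column instead of `rank` is converted to
#' per-miRNA ranks by descending score with average-rank ties.
#'
#' @param source_tables list of data.frames, one per source, with columns
#'   `mirna`, `gene` and `rank` (or `score`); an optional `source` column
#'   names the source
#' @param min_sources minimum number of sources supporting a kept pair
#'   (default 2)
#' @return data.frame of class `target_table`: `mirna`, `gene`,
#'   `aggregate_score`, `n_sources_present`, and one `rank_<source>` column
#'   per source
#' @export
aggregate_targets <- function(source_tables, min_sources = 2) {
  if (length(source_tables) < min_sources)
    stop("need at least `min_sources` tables")
  src_names <- vapply(seq_along(source_tables), function(i) {
    tb <- source_tables[[i]]
    if ("source" %in% names(tb) && length(unique(tb$source)) == 1)
      as.character(tb$source[1]) else paste0("source", i)
  }, character(1))
  tabs <- lapply(source_tables, function(tb) {
    if (!all(c("mirna", "gene") %in% names(tb)))
      stop("each table needs `mirna` and `gene` columns")
    if (!"rank" %in% names(tb)) {
      if (!"score" %in% names(tb)) stop("each table needs a `rank` or `score` column")
      tb$rank <- stats::ave(-tb$score, tb$mirna,
                            FUN = function(v) rank(v, ties.method = "average"))
    }
    if (any(tb$rank < 1)) stop("ranks must be >= 1")
    if (anyDuplicated(tb[c("mirna", "gene")]))
      stop("duplicate (mirna, gene) pair within a source")
    tb[c("mirna", "gene", "rank")]
  })
  for (i in seq_along(tabs)) names(tabs[[i]])[3] <- paste0("rank_", src_names[i])
  merged <- Reduce(function(a, b) merge(a, b, by = c("mirna", "gene"), all = TRUE),
                   tabs)
  rk <- as.matrix(merged[, -(1:2), drop = FALSE])
  n_present <- rowSums(!is.na(rk))
  score <- exp(rowMeans(log(rk), na.rm = TRUE))
  out <- cbind(merged[, 1:2], aggregate_score = score,
               n_sources_present = n_present, merged[, -(1:2), drop = FALSE])
  out <- out[n_present >= min_sources, , drop = FALSE]
  out <- out[order(out$mirna, out$aggregate_score, -out$n_sources_present,
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_table", "data.frame")
  out
}

# match signature miRNA names to target-table miRNAs; an entry without an arm
# suffix matches both -5p and -3p entries (with a warning)
.match_mirna <- function(sig_names, table_names) {
  tn <- normalize_mirna_name(table_names)
  res <- list()
  warned <- FALSE
  for (s in sig_names) {
    k <- normalize_mirna_name(s)
    hit <- which(tn == k)
    if (!length(hit) && !grepl("-(5p|3p)$", k)) {
      hit <- which(tn %in% paste0(k, c("-5p", "-3p")))
      if (length(hit)) warned <- TRUE
    }
    res[[s]] <- table_names[hit]
  }
  if (warned)
    warning("signature miRNA(s) without arm suffix matched both -5p/-3p table entries")
  res
}

#' Project consensus targets onto the disease module
#'
#' For each signature miRNA, intersects its consensus targets with the
#' module's mapped genes and flags LCC membership. Totals follow the
#' with-multiplicity convention: `total` counts every (miRNA, gene) hit,
#' `unique` counts distinct genes; likewise within the LCC. Also reports
#' genes targeted by both up- and downregulated miRNAs.
#'
#' @param targets a `target_table` from [aggregate_targets()]
#' @param module a `disease_module` with `lcc_members` filled
#' @param signature signature data.frame with `feature` and `direction`
#'   columns (e.g. from [significant_features()])
#' @return list of class `module_targets`: `hits` (mirna, direction, target,
#'   lcc_flag, aggregate_score), `totals` (total, unique, lcc_total,
#'   lcc_unique), `per_mirna` (counts), `dual_targeted` (genes hit by both
#'   directions), `missing_mirnas`
#' @export
map_targets_to_module <- function(targets, module, signature) {
  if (!length(module$mapped_genes)) stop("empty module")
  if (is.null(module$lcc_members))
    stop("module needs LCC membership; run extract_lcc() first")
  matches <- .match_mirna(signature$feature, unique(targets$mirna))
  missing <- names(matches)[lengths(matches) == 0]
  mod_up <- toupper(module$mapped_genes)
  lcc_up <- toupper(module$lcc_members)
  rows <- list()
  for (i in seq_len(nrow(signature))) {
    s <- signature$feature[i]
    tab_ids <- matches[[s]]
    if (!length(tab_ids)) next
    sub <- targets[targets$mirna %in% tab_ids, , drop = FALSE]
    hit <- toupper(sub$gene) %in% mod_up
    if (!any(hit)) next
    sub <- sub[hit, , drop = FALSE]
    rows[[s]] <- data.frame(
      mirna = s, direction = signature$direction[i],
      target = module$mapped_genes[match(toupper(sub$gene), mod_up)],
      lcc_flag = toupper(sub$gene) %in% lcc_up,
      aggregate_score = sub$aggregate_score,
      stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
          else data.frame(mirna = character(0), direction = character(0),
                          target = character(0), lcc_flag = logical(0),
                          aggregate_score = numeric(0))
  hits <- hits[!duplicated(hits[c("mirna", "target")]), , drop = FALSE]
  totals <- c(total = nrow(hits), unique = length(unique(hits$target)),
              lcc_total = sum(hits$lcc_flag),
              lcc_unique = length(unique(hits$target[hits$lcc_flag])))
  per_mirna <- if (nrow(hits))
    stats::aggregate(target ~ mirna + direction, data = hits, FUN = length)
  else data.frame(mirna = character(0), direction = character(0),
                  target = integer(0))
  names(per_mirna)[3] <- "n_targets"
  up_genes <- unique(hits$target[hits$direction == "up"])
  dn_genes <- unique(hits$target[hits$direction == "down"])
  structure(list(hits = hits, totals = totals,
                 per_mirna = per_mirna[order(-per_mirna$n_targets), , drop = FALSE],
                 dual_targeted = sort(intersect(up_genes, dn_genes)),
                 missing_mirnas = missing),
            class = "module_targets")
}

#' @export
print.module_targets <- function(x, ...) {
  t <- x$totals
  cat(sprintf("module_targets: %d hits (%d unique genes), %d in LCC (%d unique)\n",
              t["total"], t["unique"], t["lcc_total"], t["lcc_unique"]))
  invisible(x)
}

#' Connected subnetwork of miRNA targets inside the module LCC
#'
#' Induces the subgraph of `target_genes` restricted to the module's LCC,
#' returns its largest connected component with centralities and a hub list.
#'
#' @param net interactome `igraph`
#' @param module a `disease_module` with `lcc_members` filled
#' @param target_genes character vector (must lie within the mapped module)
#' @return list of class `target_subnetwork`: `members`, `graph` (igraph),
#'   `centrality` (data.frame), `hubs` (nodes in hub order); empty members
#'   with a warning when no target lies in the LCC
#' @export
target_subnetwork <- function(net, module, target_genes) {
  if (!all(toupper(target_genes) %in% toupper(module$mapped_genes)))
    stop("target_genes must lie within the mapped module")
  in_lcc <- target_genes[toupper(target_genes) %in% toupper(module$lcc_members)]
  if (!length(in_lcc)) {
    warning("no targets in the LCC")
    return(structure(list(members = character(0), graph = NULL,
                          centrality = NULL, hubs = character(0)),
                     class = "target_subnetwork"))
  }
  sub <- igraph::induced_subgraph(net, in_lcc)
  comp <- igraph::components(sub)
  sets <- split(names(comp$membership), comp$membership)
  members <- sort(sets[[which.max(lengths(sets))]])
  g <- igraph::induced_subgraph(net, members)
  cent <- node_centrality(net, members)
  structure(list(members = members, graph = g,
                 centrality = cent[order(cent$hub_rank), , drop = FALSE],
                 hubs = cent$node[order(cent$hub_rank)]),
            class = "target_subnetwork")
}

#' Write the consensus target table as TSV
#' @param targets a `target_table`
#' @param path TSV path
#' @export
write_target_table_tsv <- function(targets, path) {
  utils::write.table(as.data.frame(targets), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-miRNA module-target hits as TSV
#' @param module_targets a `module_targets` result
#' @param path TSV path (mirna, direction, target, lcc_flag, aggregate_score)
#' @export
write_module_targets_tsv <- function(module_targets, path) {
  utils::write.table(module_targets$hits, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
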