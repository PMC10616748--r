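#' Read a STRING-dialect interactome edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score`. Scores on the
#' integer 0-1000 scale are auto-detected (any score above 1) and divided by
#' 1000. Edges with score strictly greater than `min_score` are kept;
#' self-loops are dropped and symmetric duplicates merged keeping the maximum
#' score.
#'
#' @param path TSV path
#' @param min_score confidence threshold, default 0.4 (medium confidence)
#' @param score_scale `"auto"`, `"unit"` (already in 0-1) or `"milli"`
#'   (0-1000)
#' @return an undirected `igraph` with a `score` edge attribute in (0, 1]
#' @export
read_interactome <- function(path, min_score = 0.4, score_scale = "auto") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("interactome file must have columns: ", paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | is.na(df$protein1) | is.na(df$protein2) |
               df$protein1 == "" | df$protein2 == "")
  if (length(bad))
    stop("malformed interactome row(s) at line(s): ",
         paste(bad + 1, collapse = ", "))   # +1 for the header line
  scale <- score_scale
  if (identical(scale, "auto"))
    scale <- if (any(score > 1)) "milli" else "unit"
  if (identical(scale, "milli")) score <- score / 1000
  keep <- score > min_score
  df <- df[keep, , drop = FALSE]; score <- score[keep]
  if (!nrow(df)) stop("no edges above the score threshold; empty network")
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$protein1, to = df$protein2, score = score),
    directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(score = "max"))
}

#' Map a gene signature onto the interactome
#'
#' Symbols are upper-cased before matching; an optional two-column alias table
#' (`alias`, `symbol`) is applied first.
#'
#' @param net interactome `igraph`
#' @param genes character vector of query symbols
#' @param alias optional data.frame with columns `alias`, `symbol`
#' @return list of class `disease_module` with `query_genes`, `mapped_genes`,
#'   `unmapped`
#' @export
map_gene_set <- function(net, genes, alias = NULL) {
  if (!length(genes)) stop("empty gene list")
  q <- toupper(trimws(genes))
  if (!is.null(alias)) {
    m <- match(q, toupper(alias$alias))
    q[!is.na(m)] <- toupper(alias$symbol[m[!is.na(m)]])
  }
  q <- unique(q)
  nodes <- igraph::V(net)$name
  mapped <- intersect(q, toupper(nodes))
  if (!length(mapped)) stop("no query genes map to the network")
  # return node names in the graph's own case
  mapped <- nodes[match(mapped, toupper(nodes))]
  structure(list(query_genes = genes, mapped_genes = mapped,
                 unmapped = setdiff(q, toupper(nodes))),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf("disease_module: %d/%d query genes mapped", length(x$mapped_genes),
              length(unique(toupper(x$query_genes)))))
  if (!is.null(x$lcc_members))
    cat(sprintf("; LCC %d, %d peripheral component(s)", length(x$lcc_members),
                length(x$peripheral_components)))
  cat("\n"); invisible(x)
}

# induced edge count for a node-index set, via the sparse adjacency
.induced_edges <- function(adj, idx) sum(adj[idx, idx, drop = FALSE]) / 2

.sample_nodes <- function(net, size, null_model, ref_nodes) {
  nodes <- igraph::V(net)$name
  if (null_model == "uniform") return(sample(nodes, size))
  # degree-binned sampling: match the reference set's degree-decile profile
  deg <- igraph::degree(net)
  br <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
  bin <- cut(deg, breaks = br, include.lowest = TRUE)
  ref_bin <- bin[match(ref_nodes, nodes)]
  out <- character(0)
  for (b in levels(droplevels(ref_bin))) {
    need <- sum(ref_bin == b)
    pool <- nodes[bin == b]
    out <- c(out, sample(pool, min(need, length(pool))))
  }
  if (length(out) < size) out <- c(out, sample(setdiff(nodes, out), size - length(out)))
  out
}

#' Protein-protein interaction enrichment of a gene set
#'
#' Compares the number of edges inside the induced subgraph of `mapped_genes`
#' with the edge counts of `n_random` random node sets of the same size;
#' the empirical p-value is `(1 + #{null >= observed}) / (n_random + 1)`.
#'
#' @param net interactome `igraph`
#' @param mapped_genes node names (all must be in the network)
#' @param n_random null draws (>= 100 recommended for p reporting)
#' @param seed integer seed
#' @param null_model `"uniform"` (default) or `"degree"` (degree-binned)
#' @return list of class `enrichment_stat`: `observed_edges`,
#'   `expected_edges`, `empirical_p`, `average_node_degree`, `n_random`, `seed`
#' @export
ppi_enrichment <- function(net, mapped_genes, n_random = 1000, seed = 1,
                           null_model = c("uniform", "degree")) {
  null_model <- match.arg(null_model)
  nodes <- igraph::V(net)$name
  if (!all(mapped_genes %in% nodes)) stop("mapped_genes must all be network nodes")
  if (length(mapped_genes) < 2) stop("need at least 2 mapped genes")
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  idx <- match(mapped_genes, nodes)
  obs <- .induced_edges(adj, idx)
  null <- withr::with_seed(seed, vapply(seq_len(n_random), function(i) {
    s <- .sample_nodes(net, length(mapped_genes), null_model, mapped_genes)
    .induced_edges(adj, match(s, nodes))
  }, numeric(1)))
  structure(list(observed_edges = obs, expected_edges = mean(null),
                 empirical_p = (1 + sum(null >= obs)) / (n_random + 1),
                 average_node_degree = 2 * obs / length(mapped_genes),
                 n_random = n_random, seed = seed, null_model = null_model),
            class = "enrichment_stat")
}

#' Split a mapped gene set into its largest connected component and periphery
#'
#' Connected components of the induced subgraph; the largest is the LCC (on
#' ties, the component whose sorted member vector is lexicographically
#' smallest), the rest are peripheral components. Together with isolated
#' mapped nodes they partition the mapped set.
#'
#' @param net interactome `igraph`
#' @param module a `disease_module` from [map_gene_set()] (or a character
#'   vector of node names)
#' @return the `disease_module` with `lcc_members` and
#'   `peripheral_components` filled
#' @export
extract_lcc <- function(net, module) {
  if (is.character(module))
    module <- structure(list(query_genes = module, mapped_genes = module,
                             unmapped = character(0)), class = "disease_module")
  sub <- igraph::induced_subgraph(net, module$mapped_genes)
  comp <- igraph::components(sub)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  sizes <- lengths(sets)
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    firsts <- vapply(sets[big], `[`, character(1), 1)
    big <- big[order(firsts)][1]
  }
  module$lcc_members <- sets[[big]]
  module$peripheral_components <- unname(sets[-big][order(-sizes[-big])])
  module
}

#' Topological coherence of a gene set on the interactome
#'
#' The mean shortest-path length over all unordered pairs of the set's nodes
#' (unweighted hops on the full network; disconnected pairs excluded) is
#' compared with `n_random` random same-size node sets under the same
#' finite-pair rule; `z = (l_mean - mean_null) / sd_null`, significant when
#' `z < z_cutoff` (default -1.65).
#'
#' @param net interactome `igraph`
#' @param mapped_genes node names, all present in the network
#' @param n_random null draws
#' @param seed integer seed
#' @param z_cutoff significance cutoff (default -1.65)
#' @param null_model `"uniform"` (default) or `"degree"`
#' @return list of class `coherence_result`: `l_mean`, `l_rand_mean`,
#'   `l_rand_sd`, `z_score`, `significant`, `n_random`, `seed`
#' @export
module_coherence <- function(net, mapped_genes, n_random = 1000, seed = 1,
                             z_cutoff = -1.65,
                             null_model = c("uniform", "degree")) {
  null_model <- match.arg(null_model)
  nodes <- igraph::V(net)$name
  if (!all(mapped_genes %in% nodes)) stop("mapped_genes must all be network nodes")
  nv <- igraph::vcount(net)
  Dfull <- if (nv <= 4000) igraph::distances(net) else NULL
  pair_mean <- function(set) {
    D <- if (is.null(Dfull)) igraph::distances(net, v = set, to = set)
         else Dfull[set, set, drop = FALSE]
    v <- D[upper.tri(D)]
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  l_obs <- pair_mean(mapped_genes)
  if (is.na(l_obs)) stop("no finite node pairs in the module")
  null <- withr::with_seed(seed, vapply(seq_len(n_random), function(i)
    pair_mean(.sample_nodes(net, length(mapped_genes), null_model, mapped_genes)),
    numeric(1)))
  mu <- mean(null, na.rm = TRUE); sdv <- stats::sd(null, na.rm = TRUE)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else (l_obs - mu) / sdv
  structure(list(l_mean = l_obs, l_rand_mean = mu, l_rand_sd = sdv,
                 z_score = z, significant = !is.na(z) && z < z_cutoff,
                 n_random = n_random, seed = seed, null_model = null_model),
            class = "coherence_result")
}

#' Degree and betweenness centrality with hub ranking
#'
#' By default computed on the induced subgraph of `node_set` (module-internal
#' convention); set `scope = "network"` for full-network centralities
#' restricted to the set. Betweenness is normalized by `(n-1)(n-2)/2`.
#' Hub rank: descending degree, ties broken by betweenness then name.
#'
#' @param net interactome `igraph`
#' @param node_set node names
#' @param scope `"module"` (induced subgraph, default) or `"network"`
#' @return data.frame: `node`, `degree`, `betweenness`, `hub_rank`
#' @export
node_centrality <- function(net, node_set, scope = c("module", "network")) {
  scope <- match.arg(scope)
  if (!all(node_set %in% igraph::V(net)$name))
    stop("node_set must all be network nodes")
  g <- if (scope == "module") igraph::induced_subgraph(net, node_set) else net
  deg <- igraph::degree(g)
  btw <- if (igraph::vcount(g) > 2)
    igraph::betweenness(g, normalized = TRUE) else
    stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  deg <- deg[node_set]; btw <- btw[node_set]
  ord <- order(-deg, -btw, node_set)
  rank_tbl <- integer(length(node_set)); rank_tbl[ord] <- seq_along(ord)
  data.frame(node = node_set, degree = unname(deg), betweenness = unname(btw),
             hub_rank = rank_tbl, stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a gene list (one symbol per line, blank lines and `#` comments ignored)
#' @param path text file path
#' @return character vector
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a module as GraphML with lcc/degree/betweenness node attributes
#' @param net interactome `igraph`
#' @param module a `disease_module` with components filled
#' @param path output GraphML path
#' @export
write_module_graphml <- function(net, module, path) {
  g <- igraph::induced_subgraph(net, module$mapped_genes)
  cent <- node_centrality(net, module$mapped_genes)
  m <- match(igraph::V(g)$name, cent$node)
  igraph::V(g)$lcc_member <- igraph::V(g)$name %in% module$lcc_members
  igraph::V(g)$degree <- cent$degree[m]
  igraph::V(g)$betweenness <- cent$betweenness[m]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the component partition of a module as TSV
#' @param module a `disease_module` with components filled
#' @param path TSV path (`gene`, `component`; component 1 is the LCC)
#' @export
write_components_tsv <- function(module, path) {
  comps <- c(list(module$lcc_members), module$peripheral_components)
  df <- data.frame(
    gene = unlist(comps),
    component = rep(seq_along(comps), lengths(comps)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
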