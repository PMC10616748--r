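write_edges <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

triangle <- function() igraph::make_graph(~ A - B, B - C, A - C)
path3 <- function() igraph::make_graph(~ A - B, B - C)

test_that("interactome reader applies the strict score threshold on the 0-1000 scale", {
  p <- write_edges(data.frame(protein1 = c("A", "A", "B"),
                              protein2 = c("B", "C", "C"),
                              combined_score = c(390, 410, 950)))
  g <- read_interactome(p)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)                       # 390 (=0.39) excluded
  expect_false(any(el$from == "A" & el$to == "B" | el$from == "B" & el$to == "A"))
  expect_equal(sort(el$score), c(0.41, 0.95))
})

test_that("symmetric duplicates merge keeping the maximum score", {
  p <- write_edges(data.frame(protein1 = c("A", "B", "C", "D"),
                              protein2 = c("B", "A", "D", "C"),
                              combined_score = c(500, 800, 600, 450)))
  g <- read_interactome(p)
  expect_equal(igraph::ecount(g), 2)
  el <- igraph::as_data_frame(g)
  expect_equal(sort(el$score), c(0.6, 0.8))
})

test_that("k valid unique above-threshold rows give k edges; bad input errors", {
  df <- data.frame(protein1 = paste0("N", 1:7), protein2 = paste0("N", 2:8),
                   combined_score = seq(500, 800, 50))
  expect_equal(igraph::ecount(read_interactome(write_edges(df))), 7)
  bad <- df; bad$combined_score[3] <- "oops"
  expect_error(read_interactome(write_edges(bad)), "line.*4")
  low <- df; low$combined_score <- 100
  expect_error(read_interactome(write_edges(low)), "empty network")
  expect_error(read_interactome(write_edges(data.frame(a = 1, b = 2))), "columns")
})

test_that("gene mapping is case-insensitive and reports the unmapped remainder", {
  g <- triangle()
  m <- map_gene_set(g, c("a", "B", "ZZZ"))
  expect_setequal(m$mapped_genes, c("A", "B"))
  expect_equal(m$unmapped, "ZZZ")
  expect_error(map_gene_set(g, c("X", "Y")), "no query genes")
  full <- map_gene_set(g, c("A", "B", "C"))
  expect_length(full$unmapped, 0)
})

test_that("LCC and peripheral components partition the mapped set", {
  g <- igraph::make_graph(~ A - B, B - C, D - E) + igraph::vertices("F")
  mod <- extract_lcc(g, c("A", "B", "C", "D", "E", "F"))
  expect_equal(mod$lcc_members, c("A", "B", "C"))
  expect_equal(mod$peripheral_components, list(c("D", "E"), "F"))
  expect_setequal(c(mod$lcc_members, unlist(mod$peripheral_components)),
                  mod$mapped_genes)
  # fully connected module has no periphery
  full <- extract_lcc(triangle(), c("A", "B", "C"))
  expect_length(full$peripheral_components, 0)
})

test_that("PPI enrichment fixtures: clique counts and the sampling floor", {
  withr::with_seed(1, {
    g <- igraph::sample_gnp(60, 0.02)
    igraph::V(g)$name <- paste0("N", 1:60)
    clique <- paste0("C", 1:5)
    g <- g + igraph::vertices(clique)
    cp <- utils::combn(clique, 2)
    g <- igraph::add_edges(g, as.vector(cp))
  })
  enr <- ppi_enrichment(g, clique, n_random = 199, seed = 3)
  expect_equal(enr$observed_edges, 10)
  expect_equal(enr$average_node_degree, 4)
  expect_equal(enr$empirical_p, 1 / 200)   # the attainable minimum
  expect_error(ppi_enrichment(g, "N1"), "at least 2")
})

test_that("PPI enrichment p-values are calibrated for random gene sets", {
  withr::with_seed(7, {
    g <- igraph::sample_gnp(300, 0.02)
    igraph::V(g)$name <- paste0("N", 1:300)
  })
  ps <- vapply(1:100, function(i) {
    set <- withr::with_seed(1000 + i, sample(igraph::V(g)$name, 15))
    ppi_enrichment(g, set, n_random = 199, seed = i)$empirical_p
  }, numeric(1))
  rate <- mean(ps <= 0.05)
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("module coherence matches hand-computed path-length fixtures", {
  expect_equal(module_coherence(triangle(), c("A", "B", "C"), n_random = 5,
                                seed = 1)$l_mean, 1)
  expect_equal(module_coherence(path3(), c("A", "B", "C"), n_random = 5,
                                seed = 1)$l_mean, 4 / 3)
})

test_that("the full node set's coherence equals the characteristic path length", {
  withr::with_seed(12, {
    g <- igraph::sample_gnp(40, 0.15)
    igraph::V(g)$name <- paste0("N", 1:40)
    g <- igraph::induced_subgraph(g, which(igraph::components(g)$membership == 1))
  })
  coh <- module_coherence(g, igraph::V(g)$name, n_random = 5, seed = 1)
  expect_equal(coh$l_mean, igraph::mean_distance(g, directed = FALSE))
})

test_that("coherence z is invariant under node relabeling", {
  withr::with_seed(4, {
    g <- igraph::sample_gnp(80, 0.05)
    igraph::V(g)$name <- paste0("N", 1:80)
    set <- sample(igraph::V(g)$name, 10)
  })
  z1 <- module_coherence(g, set, n_random = 100, seed = 6)$z_score
  map <- stats::setNames(withr::with_seed(5, sample(igraph::V(g)$name)),
                         igraph::V(g)$name)
  g2 <- igraph::set_vertex_attr(g, "name", value = unname(map[igraph::V(g)$name]))
  z2 <- module_coherence(g2, unname(map[set]), n_random = 100, seed = 6)$z_score
  expect_equal(z1, z2)
})

test_that("centrality fixtures: star centre and path middle", {
  star <- igraph::make_graph(~ H - A, H - B, H - C, H - D)
  cent <- node_centrality(star, c("H", "A", "B", "C", "D"))
  h <- cent[cent$node == "H", ]
  expect_equal(h$degree, 4)
  expect_equal(h$betweenness, 1)
  expect_equal(h$hub_rank, 1L)
  p <- node_centrality(path3(), c("A", "B", "C"))
  expect_equal(p$betweenness[p$node == "B"], 1)
  expect_equal(p$betweenness[p$node %in% c("A", "C")], c(0, 0))
  single <- node_centrality(path3(), "A")
  expect_equal(single$degree, 0)
  expect_equal(single$betweenness, 0)
})

test_that("betweenness equals exhaustive path enumeration on small random graphs", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 4)   # 4..7 nodes
    g <- withr::with_seed(seed, igraph::sample_gnp(n, 0.5))
    igraph::V(g)$name <- paste0("N", seq_len(n))
    cent <- node_centrality(g, igraph::V(g)$name)
    oracle <- brute_betweenness(g)
    expect_equal(stats::setNames(cent$betweenness, cent$node), oracle[cent$node],
                 tolerance = 1e-10)
  }
})

test_that("graphml and component writers emit readable artifacts", {
  g <- igraph::make_graph(~ A - B, B - C, D - E)
  igraph::E(g)$score <- 0.9
  mod <- extract_lcc(g, map_gene_set(g, c("A", "B", "C", "D", "E")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_module_graphml(g, mod, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B", "C", "D", "E"))
  expect_equal(sum(igraph::V(back)$lcc_member), 3)
  write_components_tsv(mod, tsv)
  comp <- utils::read.delim(tsv)
  expect_equal(sum(comp$component == 1), 3)
})
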