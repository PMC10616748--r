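small_cfg <- function(...) {
  base <- list(n_features = 100, n_samples = 20, n_cases = 8,
               n_de_up = 4, n_de_down = 4, n_de_shared_up = 3,
               n_de_shared_down = 2, n_de_vitd_only = 3,
               hemolysis_samples = 2)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

test_that("generated dataset has config-forced shape and truth sizes", {
  ds <- generate_ct_dataset(small_cfg(), seed = 7)
  expect_equal(dim(ds$ct), c(100L, 20L))
  expect_equal(sum(ds$ct$metadata$group == "case"), 8)
  expect_length(ds$truth$de_up_ids, 4)
  expect_length(ds$truth$de_down_ids, 4)
  expect_length(ds$truth$hemolysed_ids, 2)
  expect_length(intersect(ds$truth$de_up_ids, ds$truth$de_down_ids), 0)
  # proxies always present
  expect_true(all(c("hsa-miR-23a", "hsa-miR-451a") %in% feature_ids(ds$ct)))
})

test_that("identical seed gives bit-identical output; nondetect_rate 0 masks nothing", {
  a <- generate_ct_dataset(small_cfg(), seed = 3)
  b <- generate_ct_dataset(small_cfg(), seed = 3)
  expect_identical(a, b)
  c2 <- generate_ct_dataset(small_cfg(nondetect_rate = 0), seed = 3)
  expect_false(any(c2$ct$nondetect))
})

test_that("infeasible configs are rejected", {
  expect_error(synthetic_config(n_samples = 10, n_cases = 10), "n_cases")
  expect_error(synthetic_config(n_features = 10, n_de_up = 6, n_de_down = 6),
               "exceed")
  expect_error(synthetic_config(nondetect_rate = 1.2), "nondetect_rate")
})

test_that("planted case-control shift is recovered within Monte-Carlo error", {
  # vitd_effect_ct = 0: the shared features otherwise carry an extra
  # vitamin-D shift that is confounded with case status by construction
  cfg <- small_cfg(effect_size_ct = 2, noise_sd = 0.1, n_hidden_factors = 0,
                   nondetect_rate = 0, hemolysis_samples = 0,
                   vitd_effect_ct = 0)
  for (seed in 1:5) {
    ds <- generate_ct_dataset(cfg, seed = seed)
    case <- ds$ct$metadata$group == "case"
    for (f in ds$truth$de_up_ids) {
      d <- mean(ds$ct$values[f, case]) - mean(ds$ct$values[f, !case])
      se <- 0.1 * sqrt(1 / sum(case) + 1 / sum(!case))
      expect_lt(abs(d - (-2)), 3 * se)
    }
  }
})

test_that("haemolysed samples have delta-Cq above 5", {
  ds <- generate_ct_dataset(small_cfg(), seed = 11)
  hem <- hemolysis_assess(ds$ct)
  expect_true(all(hem$delta_cq[hem$sample_id %in% ds$truth$hemolysed_ids] > 5))
})

test_that("planted PPI module is a clique at module_p = 1 and exclusive at background_p = 0", {
  ppi <- generate_ppi(30, background_p = 0.05, module_size = 5, module_p = 1, seed = 2)
  sub <- igraph::induced_subgraph(ppi$graph, ppi$truth$module_nodes)
  expect_equal(igraph::ecount(sub), 10)
  ppi0 <- generate_ppi(30, background_p = 0, module_size = 6, module_p = 0.8, seed = 2)
  el <- igraph::as_edgelist(ppi0$graph)
  expect_true(all(el %in% ppi0$truth$module_nodes))
  expect_error(generate_ppi(30, 0.1, module_size = 1, module_p = 0.5), "module_size")
  expect_error(generate_ppi(30, 0.5, module_size = 5, module_p = 0.1), "module_p")
})

test_that("planted module is denser than random same-size sets", {
  ppi <- generate_ppi(500, background_p = 0.01, module_size = 20, module_p = 0.3,
                      seed = 5)
  adj <- igraph::as_adjacency_matrix(ppi$graph, sparse = TRUE)
  nodes <- igraph::V(ppi$graph)$name
  count_edges <- function(set) sum(adj[match(set, nodes), match(set, nodes)]) / 2
  obs <- count_edges(ppi$truth$module_nodes)
  null <- withr::with_seed(99, replicate(200, count_edges(sample(nodes, 20))))
  expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("target tables place planted pairs above decoys and only in carrier sources", {
  mirs <- paste0("m", 1:5); genes <- paste0("G", 1:50)
  pm <- list(m1 = c("G1", "G2"), m2 = c("G3"))
  tabs <- generate_target_tables(mirs, genes, pm, rank_noise = 0, seed = 4)
  all_rows <- do.call(rbind, tabs)
  for (m in names(pm)) for (g in pm[[m]]) {
    carriers <- unique(all_rows$source[all_rows$mirna == m & all_rows$gene == g])
    expect_gte(length(carriers), 2)
    for (s in carriers) {
      tb <- all_rows[all_rows$source == s & all_rows$mirna == m, ]
      planted_in <- intersect(pm[[m]], tb$gene)
      decoys <- setdiff(tb$gene, pm[[m]])
      expect_lt(mean(tb$rank[tb$gene %in% planted_in]),
                mean(tb$rank[tb$gene %in% decoys]))
    }
  }
  expect_warning(generate_target_tables(mirs, genes, list(), seed = 1), "decoys only")
})

test_that("consensus aggregation recovers planted pairs at moderate rank noise", {
  withr::with_seed(21, {
    mirs <- paste0("m", 1:10)
    genes <- paste0("G", 1:200)
    pm <- stats::setNames(lapply(mirs, function(m) sample(genes, 10)), mirs)
  })
  recovered <- vapply(1:5, function(seed) {
    tabs <- generate_target_tables(mirs, genes, pm, rank_noise = 2, seed = seed)
    agg <- aggregate_targets(tabs)
    keys <- paste(agg$mirna, agg$gene)
    truth <- unlist(lapply(mirs, function(m) paste(m, pm[[m]])))
    mean(truth %in% keys)
  }, numeric(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("annotation sets honour overlap and count contracts", {
  genes <- paste0("G", 1:300)
  module <- paste0("G", 1:40)
  sets <- generate_annotation_sets(genes, module, enriched_set_overlap = 1,
                                  n_sets = 10, seed = 6)
  expect_length(sets, 10)
  expect_true(all(module %in% sets[[attr(sets, "designated")]]))
  expect_error(generate_annotation_sets(genes, module, set_size_range = c(10, 500)),
               "exceed")
})

test_that("designated annotation set attains the smallest enrichment p", {
  genes <- paste0("G", 1:300)
  module <- paste0("G", 1:40)
  wins <- vapply(1:50, function(seed) {
    sets <- generate_annotation_sets(genes, module, enriched_set_overlap = 0.8,
                                    n_sets = 10, seed = seed)
    enr <- hypergeometric_enrichment(module, sets, genes)
    enr$set_id[1] == attr(sets, "designated")
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("generated STRING files round-trip through the network reader", {
  ppi <- generate_ppi(40, 0.1, 6, 0.9, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_string_tsv(ppi$graph, path)
  g2 <- read_interactome(path)
  expect_equal(igraph::ecount(g2), igraph::ecount(ppi$graph))
  expect_setequal(igraph::V(g2)$name, igraph::V(ppi$graph)$name[igraph::degree(ppi$graph) > 0])
  # scores survive to 1/1000 resolution
  e1 <- igraph::as_data_frame(ppi$graph); e2 <- igraph::as_data_frame(g2)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_equal(e2$score[order(key(e2))], e1$score[order(key(e1))], tolerance = 1e-3)
})

test_that("rank-table and truth writers round-trip", {
  mirs <- paste0("m", 1:3); genes <- paste0("G", 1:30)
  tabs <- generate_target_tables(mirs, genes, list(m1 = "G1"), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_tables_tsv(tabs, path)
  back <- read_rank_tables_tsv(path)
  expect_equal(do.call(rbind, back)[order(1)], do.call(rbind, tabs)[order(1)],
               ignore_attr = TRUE)
})
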