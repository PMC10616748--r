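rand_expr <- function(p, n, seed = 1, sd = 1) {
  withr::with_seed(seed, matrix(rnorm(p * n, sd = sd), p, n,
    dimnames = list(paste0("f", seq_len(p)), paste0("S", seq_len(n)))))
}

test_that("a planted orthogonal batch factor is recovered as the first surrogate variable", {
  withr::with_seed(5, {
    p <- 100; n <- 40
    group <- rep(c("case", "control"), each = n / 2)
    batch <- rnorm(n)
    load <- rnorm(p, sd = 2)
    y <- outer(load, batch) + matrix(rnorm(p * n, sd = 0.5), p, n)
    dimnames(y) <- list(paste0("f", 1:p), paste0("S", 1:n))
  })
  svs <- estimate_surrogate_variables(y, group, n_sv = 1, seed = 9)
  expect_equal(svs$n_sv, 1L)
  expect_gt(abs(cor(svs$sv[, 1], batch)), 0.9)
})

test_that("pure-noise data yields zero surrogate variables under auto selection", {
  zeros <- vapply(1:50, function(seed) {
    y <- rand_expr(60, 24, seed = seed)
    group <- rep(c("case", "control"), each = 12)
    svs <- estimate_surrogate_variables(y, group, n_sv = "auto", n_perm = 30,
                                        seed = seed)
    svs$n_sv == 0
  }, logical(1))
  expect_gte(mean(zeros), 0.9)
})

test_that("a fixed surrogate-variable count is honoured", {
  withr::with_seed(3, {
    y <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(paste0("f", 1:200), paste0("S", 1:60)))
  })
  group <- rep(c("case", "control"), each = 30)
  svs <- estimate_surrogate_variables(y, group, n_sv = 8, seed = 1)
  expect_equal(svs$n_sv, 8L)
  expect_equal(ncol(svs$sv), 8L)
})

test_that("batch removal shrinks batch correlation and preserves the planted contrast", {
  withr::with_seed(17, {
    p <- 100; n <- 40
    group <- rep(c("case", "control"), each = n / 2)
    batch <- rnorm(n)
    load <- rnorm(p, sd = 1.5)
    effect <- 1.2
    y <- outer(load, batch) + matrix(rnorm(p * n, sd = 0.5), p, n)
    y[1:10, group == "case"] <- y[1:10, group == "case"] + effect
    dimnames(y) <- list(paste0("f", 1:p), paste0("S", 1:n))
  })
  svs <- estimate_surrogate_variables(y, group, n_sv = 1, seed = 2)
  adj <- remove_unwanted_variation(y, svs, primary = group)
  raw_cors <- abs(apply(y, 1, cor, y = batch))
  cors <- abs(apply(adj, 1, cor, y = batch))
  # after removal, batch correlation drops to the chance level for n = 40
  # (median |cor| of independent noise is about 0.11), far below the raw level
  expect_lt(stats::median(cors), 0.2)
  expect_lt(stats::median(cors), stats::median(raw_cors) / 4)
  d <- rowMeans(adj[1:10, group == "case"]) - rowMeans(adj[1:10, group == "control"])
  expect_lt(abs(mean(d) - effect), 0.3)   # contrast preserved on average
  expect_true(all(d > 0.5))               # and never shrunk toward zero
  # zero SVs and no nuisance: identity
  none <- structure(list(n_sv = 0L, sv = NULL, method = "sva-be"), class = "sv_set")
  expect_identical(remove_unwanted_variation(y, none, primary = group), y)
})

test_that("collinear designs are rejected with the offending columns named", {
  y <- rand_expr(10, 12, seed = 2)
  group <- rep(c("case", "control"), each = 6)
  nuis <- data.frame(copy = as.integer(group == "case"))
  expect_error(remove_unwanted_variation(y, NULL, primary = group, nuisance = nuis),
               "collinear")
})

test_that("rank products equal brute-force geometric means of pairing ranks", {
  withr::with_seed(42, {
    expr <- matrix(rnorm(8 * 8), 8, 8,
                   dimnames = list(paste0("f", 1:8), paste0("S", 1:8)))
  })
  groups <- rep(c("case", "control"), each = 4)
  de <- rank_product_test(expr, groups, n_perm = 50, seed = 1)
  expect_equal(de$table$rp_up, unname(brute_rank_product(expr, 1:4, 5:8, "up")))
  expect_equal(de$table$rp_down, unname(brute_rank_product(expr, 1:4, 5:8, "down")))
  expect_true(all(de$table$rp_up >= 1), all(de$table$rp_down >= 1))
})

test_that("a feature extreme in every comparison attains the minimum rank product", {
  expr <- rand_expr(6, 8, seed = 7)
  expr[3, 1:4] <- expr[3, 1:4] + 100   # hugely up in all cases
  groups <- rep(c("case", "control"), each = 4)
  de <- rank_product_test(expr, groups, n_perm = 50, seed = 1)
  expect_equal(de$table$rp_up[3], 1)
})

test_that("rank product is direction-symmetric and seed-reproducible", {
  expr <- rand_expr(12, 10, seed = 3)
  groups <- rep(c("case", "control"), c(5, 5))
  a <- rank_product_test(expr, groups, n_perm = 100, seed = 5)
  b <- rank_product_test(-expr, groups, n_perm = 100, seed = 5)
  expect_equal(a$table$rp_up, b$table$rp_down)
  expect_equal(a$table$rp_down, b$table$rp_up)
  expect_identical(a$table, rank_product_test(expr, groups, n_perm = 100, seed = 5)$table)
})

test_that("pfp is non-decreasing along each direction's rank ordering", {
  expr <- rand_expr(30, 12, seed = 9)
  groups <- rep(c("case", "control"), each = 6)
  de <- rank_product_test(expr, groups, n_perm = 200, seed = 2)
  for (dir in c("up", "down")) {
    ord <- order(de$table[[paste0("rp_", dir)]])
    pfp <- de$table[[paste0("pfp_", dir)]][ord]
    expect_true(all(diff(pfp) >= -1e-12))
    expect_true(all(pfp >= 0 & pfp <= 1))
  }
})

test_that("fold change follows the Ct-scale doubling convention", {
  v <- rbind(f1 = c(24, 24, 25, 25), f2 = c(25, 25, 25, 25))
  colnames(v) <- paste0("S", 1:4)
  groups <- c("case", "case", "control", "control")
  fc <- fold_change_ct(v, groups)
  expect_equal(unname(fc["f1"]), 2)   # case one cycle earlier = twofold up
  expect_equal(unname(fc["f2"]), 1)
  expect_error(fold_change_ct(v, rep("case", 4)), "empty group")
})

test_that("a planted 1.5-fold shift on the Ct scale is recovered", {
  eff <- log2(1.5)
  fcs <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      v <- matrix(rnorm(1 * 60, 25, 0.3), 1, 60)
      v[1, 1:30] <- v[1, 1:30] - eff
      dimnames(v) <- list("f1", paste0("S", 1:60))
    })
    fold_change_ct(v, rep(c("case", "control"), each = 30))
  }, numeric(1))
  se <- stats::sd(fcs) / sqrt(length(fcs))
  expect_lt(abs(mean(fcs) - 1.5), 3 * se + 0.01)
})

test_that("significant_features applies the pfp cutoff and single-call rule", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    rp_up = c(1, 5, 9), rp_down = c(9, 5, 1),
                    rank_up = 1:3, rank_down = 3:1,
                    pfp_up = c(0.01, 1, 0.9), pfp_down = c(0.9, 1, 0.02),
                    fold_change = c(2, 1, 0.5))
  de <- structure(list(table = tab, n_perm = 100, n_comparisons = 4,
                       case = "case", seed = 1), class = "de_result")
  sig <- significant_features(de, fdr = 0.05)
  expect_equal(sig$feature, c("a", "c"))
  expect_equal(sig$direction, c("up", "down"))
  expect_equal(anyDuplicated(sig$feature), 0L)
  # all pfp at 1: empty signature
  tab$pfp_up <- tab$pfp_down <- 1
  de$table <- tab
  expect_equal(nrow(significant_features(de)), 0L)
})

test_that("signature intersection matches by normalized name and keeps both annotations", {
  a <- data.frame(feature = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                  direction = c("up", "down", "up"),
                  fold_change = c(1.5, 0.8, 1.2), fdr = c(0.001, 0.01, 0.04))
  b <- data.frame(feature = c("MIR-2", "mir-3"),
                  direction = c("down", "up"),
                  fold_change = c(0.75, 1.3), fdr = c(0.02, 0.005))
  out <- intersect_signatures(a, b)
  expect_equal(out$feature, c("hsa-miR-2", "hsa-miR-3"))   # ordered by fdr_a
  expect_equal(out$direction_b, c("down", "up"))
  expect_equal(nrow(intersect_signatures(a, a[0, ])), 0L)
  ident <- intersect_signatures(a, a)
  expect_equal(ident$feature, a$feature[order(a$fdr)])
})
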