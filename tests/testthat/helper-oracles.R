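# Independent oracles used across the suite. These are deliberately naive
# (loops, enumeration) and share no code with the package implementation.

# rank product by explicit loops over all case-control pairings
brute_rank_product <- function(expr, case_idx, ctrl_idx, direction = "up") {
  pairs <- expand.grid(case = case_idx, ctrl = ctrl_idx)
  p <- nrow(expr)
  logsum <- numeric(p)
  for (k in seq_len(nrow(pairs))) {
    fc <- expr[, pairs$case[k]] - expr[, pairs$ctrl[k]]
    r <- if (direction == "up") rank(-fc, ties.method = "average")
         else rank(fc, ties.method = "average")
    logsum <- logsum + log(r)
  }
  exp(logsum / nrow(pairs))
}

# exhaustive label-permutation null: rank products recomputed for every
# way of assigning n_case columns the "case" role, using all pairings.
# Returns a p x n_labelings matrix of null rank products for one direction.
exhaustive_null_rp <- function(expr, n_case, direction = "up") {
  n <- ncol(expr); p <- nrow(expr)
  sets <- utils::combn(n, n_case)
  vapply(seq_len(ncol(sets)), function(j) {
    cb <- sets[, j]
    kb <- setdiff(seq_len(n), cb)
    pairs <- expand.grid(case = cb, ctrl = kb)
    s <- numeric(p)
    for (k in seq_len(nrow(pairs))) {
      fck <- expr[, pairs$case[k]] - expr[, pairs$ctrl[k]]
      r <- if (direction == "up") rank(-fck, ties.method = "average")
           else rank(fck, ties.method = "average")
      s <- s + log(r)
    }
    exp(s / nrow(pairs))
  }, numeric(p))
}

# betweenness by exhaustive simple-path enumeration (graphs <= ~8 nodes)
brute_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  btw <- stats::setNames(numeric(n), nodes)
  if (n < 3) return(btw)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
      for (v in which(adj[last, ] > 0)) if (!v %in% path) walk(c(path, v))
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (pth in sp) for (v in pth[-c(1, length(pth))])
      btw[v] <- btw[v] + 1 / length(sp)
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# upper-tail hypergeometric by direct combinatorial summation
enum_hyper_upper <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# tiny ct_matrix builder
make_ct <- function(values, group = NULL, ...) {
  md <- NULL
  if (!is.null(group))
    md <- data.frame(sample_id = colnames(values), group = group, ...)
  ct_matrix(values, metadata = md)
}

# fixture with the two haemolysis reference assays at chosen delta-Cq values
hemolysis_fixture <- function(delta_cq) {
  n <- length(delta_cq)
  v <- rbind("hsa-miR-23a" = 14 + delta_cq, "hsa-miR-451a" = rep(14, n),
             "hsa-miR-s1" = rep(25, n))
  colnames(v) <- sprintf("S%02d", seq_len(n))
  ct_matrix(v)
}
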