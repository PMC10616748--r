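#' Estimate surrogate variables for hidden expression heterogeneity
#'
#' Two-step surrogate-variable analysis: residualize on the primary phenotype
#' (and protected covariates), estimate the number of surrogate variables by
#' Buja-Eyuboglu permutation of residual eigenvalues when `n_sv = "auto"`,
#' then refine the leading right singular vectors by significance-weighted
#' regression. Delegated to the `sva` package.
#'
#' @param expr complete numeric matrix, features x samples (or a complete
#'   [ct_matrix()])
#' @param primary factor/character of the primary phenotype, one per sample
#' @param protect optional data.frame of protected covariates (kept in the
#'   model so surrogate variables do not absorb them)
#' @param n_sv `"auto"` (permutation-based selection) or a fixed count
#' @param n_perm permutations for the eigenvalue test (default 100)
#' @param seed integer seed
#' @return list of class `sv_set`: `n_sv`, `sv` (samples x n_sv matrix, or
#'   `NULL` when `n_sv = 0`), `method`
#' @export
estimate_surrogate_variables <- function(expr, primary, protect = NULL,
                                         n_sv = "auto", n_perm = 100, seed = 1) {
  if (inherits(expr, "ct_matrix")) {
    if (any(expr$nondetect)) stop("expr must be complete (impute first)")
    expr <- expr$values
  }
  n <- ncol(expr)
  if (length(primary) != n) stop("primary length must match sample count")
  covd <- data.frame(.primary = factor(primary))
  if (!is.null(protect)) covd <- cbind(covd, protect)
  mod <- stats::model.matrix(~ ., covd)
  mod0 <- if (ncol(covd) > 1)
    stats::model.matrix(~ ., covd[, -1, drop = FALSE]) else
    stats::model.matrix(~ 1, covd)
  if (n <= ncol(mod)) stop("too few samples for the covariate model")
  withr::with_seed(seed, {
    k <- if (identical(n_sv, "auto"))
      sva::num.sv(expr, mod, method = "be", B = n_perm, seed = NULL)
    else as.integer(n_sv)
    if (k <= 0)
      return(structure(list(n_sv = 0L, sv = NULL, method = "sva-be"),
                       class = "sv_set"))
    fit <- NULL
    utils::capture.output(
      fit <- sva::sva(expr, mod, mod0, n.sv = k), type = "output")
    svm <- as.matrix(fit$sv)
    colnames(svm) <- paste0("SV", seq_len(ncol(svm)))
    rownames(svm) <- colnames(expr)
    structure(list(n_sv = ncol(svm), sv = svm, method = "sva-be"),
              class = "sv_set")
  })
}

#' Remove surrogate-variable and nuisance-covariate effects
#'
#' Fits, per feature, a linear model on the primary phenotype plus surrogate
#' variables and nuisance covariates, then subtracts only the fitted surrogate
#' and nuisance components. The primary-phenotype contrast is unchanged in
#' expectation. With zero surrogate variables and no nuisance covariates the
#' input is returned unchanged.
#'
#' @param expr complete features x samples matrix (or complete [ct_matrix()])
#' @param svs an `sv_set` from [estimate_surrogate_variables()] (or `NULL`)
#' @param primary primary phenotype, one per sample
#' @param nuisance optional data.frame of nuisance covariates to remove along
#'   with the surrogate variables (e.g. intervention arm)
#' @param keep optional data.frame of known covariates of interest that are
#'   modeled but not subtracted (e.g. a second phenotype contrast tested
#'   downstream); protecting them here and in
#'   [estimate_surrogate_variables()] stops surrogate variables from
#'   absorbing their effects
#' @return adjusted matrix (same shape; or `ct_matrix` if one was supplied)
#' @export
remove_unwanted_variation <- function(expr, svs = NULL, primary,
                                      nuisance = NULL, keep = NULL) {
  was_ct <- inherits(expr, "ct_matrix")
  ctin <- if (was_ct) expr else NULL
  if (was_ct) expr <- expr$values
  n <- ncol(expr)
  sv_mat <- if (!is.null(svs) && svs$n_sv > 0) svs$sv else NULL
  if (is.null(sv_mat) && is.null(nuisance)) {
    return(if (was_ct) ctin else expr)
  }
  covd <- data.frame(.primary = factor(primary))
  if (!is.null(keep)) covd <- cbind(covd, keep)
  n_kept_vars <- ncol(covd)            # .primary plus all kept covariates
  if (!is.null(nuisance)) covd <- cbind(covd, nuisance)
  D0 <- stats::model.matrix(~ ., covd)
  asgn <- attr(D0, "assign")           # 0 = intercept, i = i-th covd column
  D <- if (!is.null(sv_mat)) cbind(D0, sv_mat) else D0
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- t(qr.coef(qrD, t(expr)))                 # features x k coefficients
  prim_cols <- which(asgn <= n_kept_vars)       # intercept, primary, kept
  rem_cols <- setdiff(seq_len(ncol(D)), prim_cols)
  adj <- expr - B[, rem_cols, drop = FALSE] %*% t(D[, rem_cols, drop = FALSE])
  dimnames(adj) <- dimnames(expr)
  if (was_ct) ct_matrix(adj, nondetect = ctin$nondetect, qc_flag = ctin$qc_flag,
                        metadata = ctin$metadata) else adj
}

#' Rank-product differential expression with permutation pfp
#'
#' For every feature, the rank product in each direction is the geometric mean
#' of its fold-change ranks across case-control comparisons (one case paired
#' with one control per comparison; all pairings, subsampled to
#' `max_comparisons` when there are more). The null distribution comes from
#' `n_perm` permutations of the sample labels: each permutation reassigns the
#' case/control roles at random and recomputes the rank products over the
#' same pairing structure, so the dependence between comparisons that share a
#' sample is preserved. The percentage of false prediction (pfp) at a feature
#' is the expected number of null rank products at least as extreme divided
#' by the feature's rank, monotonized step-up along each direction's ordering
#' and clipped to `[0, 1]`.
#'
#' `expr` is on the expression scale (higher = more abundant); pass the
#' negated Ct matrix so that "up" means lower Ct. Since qPCR Ct is a log2
#' scale, the linear fold change is `2^(mean case - mean control)` of `expr`.
#'
#' @param expr complete features x samples matrix on the expression scale
#' @param groups two-level labels, one per sample
#' @param case the level treated as "case" (default `"case"` if present,
#'   otherwise the first level)
#' @param n_perm permutations for the null (default 1000; fewer than 10 warns)
#' @param max_comparisons cap on case-control pairings (default 50, sampled
#'   with the seed; exhaustive when there are fewer)
#' @param seed integer seed for pairing subsampling and the permutation null
#' @return object of class `de_result`: `table` (feature, rp_up, rp_down,
#'   rank_up, rank_down, pfp_up, pfp_down, fold_change), plus `n_perm`,
#'   `n_comparisons`, `case`, `seed`
#' @export
rank_product_test <- function(expr, groups, case = NULL, n_perm = 1000,
                              max_comparisons = 50, seed = 1) {
  if (inherits(expr, "ct_matrix")) {
    if (any(expr$nondetect)) stop("expr must be complete (impute first)")
    expr <- expr$values
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) stop("groups length must match samples")
  lev <- unique(groups)
  if (length(lev) != 2) stop("groups must have exactly two levels")
  if (is.null(case)) case <- if ("case" %in% lev) "case" else lev[1]
  ctrl <- setdiff(lev, case)
  ci <- which(groups == case); ki <- which(groups == ctrl)
  if (length(ci) < 2 || length(ki) < 2) stop("each group needs >= 2 samples")
  if (n_perm < 10) warning("n_perm < 10: pfp estimates will be unstable")
  p <- nrow(expr)

  withr::with_seed(seed, {
    pairs <- expand.grid(case = ci, ctrl = ki)
    if (nrow(pairs) > max_comparisons)
      pairs <- pairs[sample.int(nrow(pairs), max_comparisons), ]
    K <- nrow(pairs)
    fc <- expr[, pairs$case, drop = FALSE] - expr[, pairs$ctrl, drop = FALSE]
    r_up <- apply(-fc, 2, rank, ties.method = "average")
    r_dn <- apply(fc, 2, rank, ties.method = "average")
    rp_up <- exp(rowMeans(log(r_up)))
    rp_dn <- exp(rowMeans(log(r_dn)))

    # label-permutation null over the same pairing structure: pairings that
    # share a sample stay correlated under the null, exactly as observed
    n <- ncol(expr); nc <- length(ci)
    ai <- match(pairs$case, ci); bi <- match(pairs$ctrl, ki)
    null_up <- numeric(n_perm * p); null_dn <- numeric(n_perm * p)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      cb <- perm[seq_len(nc)]; kb <- perm[(nc + 1):n]
      s_up <- numeric(p); s_dn <- numeric(p)
      for (k in seq_len(K)) {
        ru <- rank(expr[, kb[bi[k]]] - expr[, cb[ai[k]]],
                   ties.method = "average")        # rank of -fc = "up" rank
        s_up <- s_up + log(ru)
        s_dn <- s_dn + log(p + 1 - ru)             # average-tie reflection
      }
      idx <- ((b - 1) * p + 1):(b * p)
      null_up[idx] <- exp(s_up / K)
      null_dn[idx] <- exp(s_dn / K)
    }

    pfp_of <- function(rp, null_pool) {
      null_sorted <- sort(null_pool)
      rnk <- rank(rp, ties.method = "average")
      # tolerance so null values float-equal to an observed rp count as ties
      e_false <- findInterval(rp + 1e-9, null_sorted) / n_perm
      pfp <- e_false / rnk
      ord <- order(rp)
      adj <- rev(cummin(rev(pfp[ord])))   # step-up: non-decreasing along ranks
      out <- numeric(p); out[ord] <- adj
      list(pfp = pmin(out, 1), rank = rnk)
    }
    up <- pfp_of(rp_up, null_up); dn <- pfp_of(rp_dn, null_dn)
    fcase <- rowMeans(expr[, ci, drop = FALSE])
    fctrl <- rowMeans(expr[, ki, drop = FALSE])
    tab <- data.frame(
      feature = rownames(expr) %||% paste0("f", seq_len(p)),
      rp_up = rp_up, rp_down = rp_dn,
      rank_up = up$rank, rank_down = dn$rank,
      pfp_up = up$pfp, pfp_down = dn$pfp,
      fold_change = 2^(fcase - fctrl),
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(table = tab, n_perm = n_perm, n_comparisons = K,
                   case = case, seed = seed),
              class = "de_result")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d features, %d comparisons, %d permutations (case = %s)\n",
              nrow(x$table), x$n_comparisons, x$n_perm, x$case))
  invisible(x)
}

#' Linear fold change from Ct-scale group means
#'
#' `FC = 2^(mean Ct_control - mean Ct_case)`; a fold change above 1 means
#' higher abundance (lower Ct) in cases.
#'
#' @param ct_values features x samples matrix of Ct values (or [ct_matrix()])
#' @param groups two-level labels
#' @param case level treated as case (default `"case"` if present)
#' @return named numeric vector of per-feature fold changes
#' @export
fold_change_ct <- function(ct_values, groups, case = NULL) {
  if (inherits(ct_values, "ct_matrix")) ct_values <- ct_values$values
  groups <- as.character(groups)
  lev <- unique(groups)
  if (is.null(case)) case <- if ("case" %in% lev) "case" else lev[1]
  ctrl <- setdiff(lev, case)
  if (!sum(groups == case) || !sum(groups == ctrl)) stop("empty group")
  2^(rowMeans(ct_values[, groups == ctrl, drop = FALSE]) -
     rowMeans(ct_values[, groups == case, drop = FALSE]))
}

#' Call significant features from a rank-product result
#'
#' Features with `min(pfp_up, pfp_down) < fdr`; the direction with the smaller
#' pfp wins, ties broken by the larger absolute log fold change. Each feature
#' appears at most once. Output is ordered by winning pfp.
#'
#' @param de a `de_result`
#' @param fdr pfp cutoff (default 0.05)
#' @return signature data.frame: `feature`, `direction` (up/down),
#'   `fold_change`, `fdr`
#' @export
significant_features <- function(de, fdr = 0.05) {
  tab <- de$table
  up_wins <- tab$pfp_up < tab$pfp_down |
    (tab$pfp_up == tab$pfp_down & log2(tab$fold_change) >= 0)
  win_pfp <- ifelse(up_wins, tab$pfp_up, tab$pfp_down)
  keep <- win_pfp < fdr
  sig <- data.frame(feature = tab$feature[keep],
                    direction = ifelse(up_wins[keep], "up", "down"),
                    fold_change = tab$fold_change[keep],
                    fdr = win_pfp[keep], stringsAsFactors = FALSE)
  sig[order(sig$fdr, -abs(log2(sig$fold_change))), , drop = FALSE]
}

#' Intersect two differential-expression signatures
#'
#' Features present in both signatures after miRNA-name normalization,
#' annotated with both directions and both FDRs; ordered by the first
#' signature's pfp.
#'
#' @param sig_a,sig_b signature data.frames from [significant_features()]
#' @return data.frame: `feature`, `direction_a`, `direction_b`,
#'   `fold_change_a`, `fold_change_b`, `fdr_a`, `fdr_b`
#' @export
intersect_signatures <- function(sig_a, sig_b) {
  ka <- normalize_mirna_name(sig_a$feature)
  kb <- normalize_mirna_name(sig_b$feature)
  m <- match(ka, kb)
  hit <- !is.na(m)
  out <- data.frame(feature = sig_a$feature[hit],
                    direction_a = sig_a$direction[hit],
                    direction_b = sig_b$direction[m[hit]],
                    fold_change_a = sig_a$fold_change[hit],
                    fold_change_b = sig_b$fold_change[m[hit]],
                    fdr_a = sig_a$fdr[hit], fdr_b = sig_b$fdr[m[hit]],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$fdr_a), , drop = FALSE]
}

#' Write a signature table as TSV
#' @param sig signature data.frame (feature, direction, fold_change, fdr)
#' @param path TSV path
#' @export
write_signature_tsv <- function(sig, path) {
  utils::write.table(sig, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
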