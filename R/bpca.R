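#' Bayesian-PCA imputation of a matrix with missing entries
#'
#' Variational Bayesian principal-component analysis in the style of Oba et
#' al.'s bpca: an EM iteration over the probabilistic-PCA model
#' `y = W x + mu + eps`, `x ~ N(0, I_q)`, `eps ~ N(0, 1/tau I)`, with an
#' automatic-relevance-determination prior on the columns of the loading
#' matrix (`alpha_j = d / ||w_j||^2`) that shrinks unneeded components away.
#' Missing cells are filled with their posterior mean at each iteration;
#' observed cells are never altered. Rows are observations, columns variables.
#'
#' @param x numeric matrix with `NA` for missing cells (rows = observations)
#' @param n_components latent dimension `q`; must be `< min(dim(x))`
#' @param tol convergence tolerance on the maximum absolute change of imputed
#'   values between iterations
#' @param max_iter iteration cap; non-convergence returns the current result
#'   with a warning and attribute `converged = FALSE`
#' @return completed matrix with attributes `converged`, `n_iter`,
#'   `imputed_mask`
#' @keywords internal
bpca_complete <- function(x, n_components, tol = 1e-4, max_iter = 1000) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x); d <- ncol(x)
  if (n_components >= min(n, d))
    stop("n_components must be < min(dim(x))")
  q <- n_components
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "converged") <- TRUE; attr(x, "n_iter") <- 0L
    attr(x, "imputed_mask") <- miss
    return(x)
  }
  if (any(colSums(!miss) < 2) || any(rowSums(!miss) < 1))
    stop("each column needs >= 2 observed cells and each row >= 1")

  mu <- colMeans(x, na.rm = TRUE)
  y <- x
  y[miss] <- matrix(mu, n, d, byrow = TRUE)[miss]
  sv <- svd(sweep(y, 2, mu), nu = 0, nv = q)
  if (sv$d[1] < 1e-12) stop("degenerate covariance: data has no variance")
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  resid_var <- max(mean(sweep(y, 2, mu)^2) - sum(sv$d[seq_len(q)]^2) / (n * d), 1e-8)
  tau <- 1 / resid_var
  alpha <- rep(1, q)

  pattern <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pattern)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    X <- matrix(0, n, q)
    Ssum <- matrix(0, q, q)
    y_new <- y
    for (rows in groups) {
      m_idx <- which(miss[rows[1], ])
      o_idx <- setdiff(seq_len(d), m_idx)
      Wo <- W[o_idx, , drop = FALSE]
      S <- solve(diag(q) + tau * crossprod(Wo))
      Yc <- sweep(x[rows, o_idx, drop = FALSE], 2, mu[o_idx])
      M <- tau * (Yc %*% Wo) %*% S
      X[rows, ] <- M
      Ssum <- Ssum + length(rows) * S
      if (length(m_idx))
        y_new[rows, m_idx] <- sweep(M %*% t(W[m_idx, , drop = FALSE]), 2,
                                    mu[m_idx], `+`)
    }
    delta <- max(abs(y_new[miss] - y[miss]))
    y <- y_new
    mu <- colMeans(y)
    Yc <- sweep(y, 2, mu)
    A <- crossprod(Yc, X)
    B <- crossprod(X) + Ssum + diag(alpha, q, q) / tau
    W <- t(solve(B, t(A)))
    sse <- sum((Yc - X %*% t(W))^2) + sum(diag(crossprod(W) %*% Ssum))
    tau <- min(n * d / max(sse, 1e-12), 1e12)
    alpha <- d / pmax(colSums(W^2), 1e-12)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("bpca imputation did not converge in ", max_iter, " iterations")
  attr(y, "converged") <- converged
  attr(y, "n_iter") <- it
  attr(y, "imputed_mask") <- miss
  y
}

#' Impute nondetects in a Ct matrix by Bayesian PCA
#'
#' Fills every nondetect cell of the (normalized) Ct matrix with the
#' Bayesian-PCA posterior mean (see [bpca_complete()]); observed cells are
#' unchanged. Samples are treated as observations, features as variables.
#' Intended to run after the missingness filter, so no feature exceeds the
#' upstream missingness cutoff.
#'
#' @param ct a [ct_matrix()]
#' @param n_components latent dimension (default 5)
#' @param tol,max_iter convergence controls, passed to [bpca_complete()]
#' @return a complete `ct_matrix` (empty nondetect mask) with attributes
#'   `imputed_mask`, `converged`, `n_iter`
#' @export
impute_bpca <- function(ct, n_components = 5, tol = 1e-4, max_iter = 1000) {
  stopifnot(inherits(ct, "ct_matrix"))
  x <- ct$values
  x[ct$nondetect] <- NA_real_
  done <- bpca_complete(t(x), n_components = n_components, tol = tol,
                        max_iter = max_iter)
  vals <- matrix(t(done), nrow(ct$values), ncol(ct$values),
                 dimnames = dimnames(ct$values))
  out <- ct_matrix(vals, nondetect = matrix(FALSE, nrow(vals), ncol(vals)),
                   qc_flag = ct$qc_flag, metadata = ct$metadata)
  attr(out, "imputed_mask") <- ct$nondetect
  attr(out, "converged") <- attr(done, "converged")
  attr(out, "n_iter") <- attr(done, "n_iter")
  out
}
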