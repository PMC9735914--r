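# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Symmetry / PSD check with numerical slack.
check_cov_matrix <- function(M, name = "covariance matrix", tol = 1e-8) {
  stop_if_not(is.matrix(M) && nrow(M) == ncol(M), "%s must be square", name)
  stop_if_not(max(abs(M - t(M))) < 1e-6 * (1 + max(abs(M))),
              "%s must be symmetric", name)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -tol * (1 + max(abs(ev))),
              "%s must be positive semi-definite", name)
  invisible(TRUE)
}

# Sample from a scaled-inverse-chi-square(df, scale) distribution:
# X = df * scale / chisq(df).
rscinvchisq <- function(n, df, scale) {
  df * scale / stats::rchisq(n, df)
}

# Inverse-Wishart(nu, S) sample (density proportional to
# |X|^{-(nu+p+1)/2} exp(-tr(S X^{-1})/2)); mean S/(nu-p-1) for nu > p+1.
rinvwishart <- function(nu, S) {
  p <- nrow(S)
  W <- stats::rWishart(1, df = nu, Sigma = chol2inv(chol(S)))[, , 1]
  X <- chol2inv(chol(W))
  (X + t(X)) / 2
}

# Symmetric matrix square root via eigendecomposition, tolerating a PSD
# matrix with (numerically) zero eigenvalues.
sym_sqrt <- function(M) {
  if (all(M[row(M) != col(M)] == 0))
    return(diag(sqrt(pmax(diag(M), 0)), nrow(M)))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

# Draw n x t matrix whose rows are iid N(0, Sigma).
rmat_norm_rows <- function(n, Sigma) {
  t_ <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * t_), n, t_)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) Z %*% sym_sqrt(Sigma) else Z %*% R
}
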