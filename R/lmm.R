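# Univariate mixed models: plot-level BLUP model and spectral REML GBLUP.

#' Fit the plot-level model y_ij = mu + G_i + B_j + e_ij
#'
#' Block is fixed, genotype random iid; variance components are estimated by
#' REML (via lme4). The shrunken genotype BLUPs are the adjusted phenotypes
#' used by the downstream prediction models.
#'
#' @param records data.frame with columns `line_id`, `block`, `value`
#'   (one population, environment and trait).
#' @return a `plot_model_fit`: `mu`, `block_effects`, `blups` (named per
#'   line), `sigma2_G`, `sigma2_e`, `h2_line` (plot-level heritability).
#' @export
fit_plot_model <- function(records) {
  stop_if_not(all(c("line_id", "block", "value") %in% names(records)),
              "records must have line_id, block, value columns")
  records <- records[!is.na(records$value), ]
  stop_if_not(length(unique(records$block)) >= 2,
              "need >= 2 blocks; block effect is confounded with the mean otherwise")
  stop_if_not(length(unique(records$line_id)) >= 2, "need >= 2 lines")
  records$block <- factor(records$block)
  records$line_id <- factor(records$line_id)
  fit <- suppressMessages(lme4::lmer(value ~ block + (1 | line_id),
                                     data = records, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_G <- vc$vcov[vc$grp == "line_id"]
  sigma2_e <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  blups <- lme4::ranef(fit)$line_id[, 1]
  names(blups) <- rownames(lme4::ranef(fit)$line_id)
  structure(list(mu = unname(fe[1]),
                 block_effects = fe[-1],
                 blups = blups,
                 sigma2_G = sigma2_G,
                 sigma2_e = sigma2_e,
                 h2_line = sigma2_G / (sigma2_G + sigma2_e)),
            class = "plot_model_fit")
}

# Restricted log-likelihood of the GBLUP model, profiled over sigma2_g,
# as a function of delta = sigma2_e / sigma2_g, in the spectral
# parameterization: xi are eigenvalues of P K P restricted to the
# fixed-effect complement, eta the rotated data.
gblup_profile_reml <- function(delta, xi, eta2) {
  np <- length(xi)
  s2g <- sum(eta2 / (xi + delta)) / np
  -0.5 * (np * (log(2 * pi * s2g) + 1) + sum(log(xi + delta)))
}

#' GBLUP by spectral REML
#'
#' Fits y = mu + u + e with u ~ N(0, sigma2_g K) on the phenotyped lines by
#' restricted maximum likelihood: after one eigendecomposition of the
#' intercept-projected training kinship, the restricted likelihood is
#' profiled over the variance ratio delta = sigma2_e / sigma2_g and
#' maximized by a bounded golden-section search (relative tolerance 1e-8 on
#' log delta). Breeding values for unphenotyped lines are conditional means
#' through the cross-block of K.
#'
#' @param y named numeric vector over the lines of `K`; NA marks
#'   unphenotyped lines.
#' @param K a `grm` object or plain PSD matrix aligned to `y`.
#' @return a `gblup_fit`: `mu`, `u_hat` (all lines), `sigma2_g`, `sigma2_e`,
#'   `h2`, `loglik_restricted`, `delta`.
#' @export
fit_gblup <- function(y, K) {
  if (inherits(K, "grm")) K <- K$matrix
  n_all <- nrow(K)
  stop_if_not(length(y) == n_all, "y must align with K")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stop_if_not(ev_min > -1e-6 * (1 + max(abs(diag(K)))),
              "K is not positive semi-definite")
  obs <- which(!is.na(y))
  stop_if_not(length(obs) >= 3, "need >= 3 phenotyped lines")
  yo <- y[obs]
  Ko <- K[obs, obs, drop = FALSE]
  n <- length(obs)

  # project out the intercept, then eigendecompose
  Pc <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(Pc %*% Ko %*% Pc, symmetric = TRUE)
  keep <- seq_len(n - 1)                      # drop the null direction
  xi <- pmax(e$values[keep], 0)
  eta <- drop(crossprod(e$vectors[, keep, drop = FALSE], yo))
  eta2 <- eta^2

  opt <- stats::optimize(function(ld) gblup_profile_reml(exp(ld), xi, eta2),
                         interval = c(log(1e-8), log(1e8)),
                         maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  sigma2_g <- sum(eta2 / (xi + delta)) / (n - 1)
  sigma2_e <- delta * sigma2_g
  h2 <- sigma2_g / (sigma2_g + sigma2_e)

  V <- sigma2_g * Ko + sigma2_e * diag(n)
  Vinv <- chol2inv(chol(V))
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vinv %*% yo) / crossprod(one, Vinv %*% one))
  resid <- yo - mu
  u_all <- drop(sigma2_g * K[, obs, drop = FALSE] %*% (Vinv %*% resid))
  names(u_all) <- rownames(K) %||% names(y)
  structure(list(mu = mu, u_hat = u_all,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = h2, delta = delta,
                 loglik_restricted = opt$objective,
                 trained_on = obs),
            class = "gblup_fit")
}

#' Predicted values from a GBLUP fit
#' @param object a `gblup_fit`.
#' @param ... unused.
#' @return numeric vector `mu + u_hat` over all lines in the GRM.
#' @export
predict.gblup_fit <- function(object, ...) {
  object$mu + object$u_hat
}
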