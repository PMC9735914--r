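# High-dimensional factor model for trait-assisted genomic prediction.
#
# Y = 1 mu' + F Lambda' + U_r + E, where the k factor columns f_c carry the
# shared (co)variation: f_c ~ N(0, h_c K + (1 - h_c) I), i.e. each factor
# splits into a genetic part (correlated through the GRM) and a residual
# part, with the genetic share h_c sampled on a discrete grid. U_r holds
# trait-specific (idiosyncratic) genetic effects, u_rj ~ N(0, s2_gj K), so
# a trait with no shared structure still receives its own GBLUP-like
# prediction; E is trait-specific white noise. Loadings carry a
# column-wise geometrically increasing shrinkage prior so later factors
# explain less. This is a deliberately simplified factor-analytic sampler
# in the spirit of high-dimensional multi-trait packages; it aims at
# qualitative, not bit-level, agreement with them.

#' Fit the genomic factor model
#'
#' @param Y n x t matrix of line-level phenotypes (t >= 4), NA cells
#'   imputed by data augmentation.
#' @param K GRM aligned to rows of Y.
#' @param k number of factors (default 8; must be <= t).
#' @param n_iter,burn_in,thin chain controls (defaults 20000 / 5000 / 5).
#' @param seed integer seed.
#' @param h2_grid discrete grid for the factor genetic share (default
#'   0, 0.1, ..., 0.9).
#' @param shrink_base base of the geometric loading-precision ladder
#'   (column c has prior precision `shrink_base^(c-1)`, default 2).
#' @return a `factor_model_fit`: `mu`, `loadings` (t x k posterior means),
#'   `factor_h2`, `sigma2_g` (idiosyncratic genetic variances), `sigma2`
#'   (idiosyncratic residual variances), `Yhat` (posterior mean fitted
#'   values incl. masked cells), `U_gen` (posterior mean genetic values),
#'   `implied_G0`, `implied_R0`, plus refit ingredients.
#' @export
fit_factor_model <- function(Y, K, k = 8, n_iter = 20000, burn_in = 5000,
                             thin = 5, seed = 1L,
                             h2_grid = seq(0, 0.9, by = 0.1),
                             shrink_base = 2) {
  if (inherits(K, "grm")) K <- K$matrix
  Y <- as.matrix(Y)
  n <- nrow(Y); t_ <- ncol(Y)
  stop_if_not(t_ >= 4, "factor model needs >= 4 traits")
  stop_if_not(k <= t_, "k must not exceed the number of traits")
  stop_if_not(k >= 1, "k must be >= 1")
  stop_if_not(n_iter > burn_in, "n_iter must exceed burn_in")
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("T%02d", seq_len(t_))
  if (is.null(rownames(Y))) rownames(Y) <- rownames(K) %||%
      sprintf("L%03d", seq_len(n))

  set.seed(seed)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  keep <- d > 1e-8 * max(d, 1e-12)
  d[!keep] <- 0
  r_eff <- sum(keep)
  U <- eK$vectors

  vY <- apply(Y, 2, stats::var, na.rm = TRUE)
  vY[!is.finite(vY) | vY <= 0] <- 1e-6
  nu0 <- 5
  s0_e <- 0.5 * vY
  s0_g <- 0.1 * vY
  tau <- shrink_base^(seq_len(k) - 1)

  mu <- colMeans(Y, na.rm = TRUE)
  miss <- is.na(Y)
  Ycur <- Y
  Ycur[miss] <- matrix(mu, n, t_, byrow = TRUE)[miss]
  h2_init <- vapply(seq_len(t_), function(j) {
    tryCatch(min(max(fit_gblup(Y[, j], K)$h2, 0.05), 0.95),
             error = function(e) 0.5)
  }, numeric(1))
  sigma2 <- (1 - h2_init) * vY
  sigma2_g <- 0.5 * h2_init * vY
  Ustar_r <- matrix(0, n, t_)

  # SVD warm start for loadings and scores
  Yc0 <- sweep(Ycur, 2, mu)
  sv <- svd(Yc0, nu = k, nv = k)
  Fstar <- crossprod(U, sv$u %*% diag(sv$d[seq_len(k)] / sqrt(n), k))
  Lambda <- sv$v
  h <- rep(0.5, k)

  mu_sum <- numeric(t_); L_sum <- matrix(0, t_, k)
  h_sum <- numeric(k); s2_sum <- numeric(t_); s2g_sum <- numeric(t_)
  Yhat_sum <- matrix(0, n, t_); Ugen_sum <- matrix(0, n, t_)
  G0_sum <- matrix(0, t_, t_); R0_sum <- matrix(0, t_, t_)
  n_samp <- 0L

  for (it in seq_len(n_iter)) {
    ## fitted values in line space
    FL <- Fstar %*% t(Lambda) + Ustar_r
    fitted <- sweep(U %*% FL, 2, mu, `+`)

    ## 1. impute missing cells
    if (any(miss)) {
      idx <- which(miss)
      sds <- sqrt(sigma2)[col(Y)[idx]]
      Ycur[idx] <- fitted[idx] + stats::rnorm(length(idx), 0, sds)
    }

    ## 2. intercepts
    resid_mu <- Ycur - sweep(fitted, 2, mu)   # Ycur - U (F Lambda' + U_r)
    mu <- colMeans(resid_mu) +
      stats::rnorm(t_, 0, sqrt(sigma2 / n))

    ## 3. factor scores, column by column (eigen space)
    Ystar <- crossprod(U, sweep(Ycur, 2, mu))
    Yadj <- Ystar - Ustar_r
    R <- Yadj - Fstar %*% t(Lambda)
    for (c in seq_len(k)) {
      lam_c <- Lambda[, c]
      R <- R + tcrossprod(Fstar[, c], lam_c)
      w <- lam_c / sigma2
      a <- sum(lam_c * w)                     # sum lam^2 / sigma2
      v_c <- h[c] * d + (1 - h[c])
      prec <- a + 1 / v_c
      rhs <- drop(R %*% w)
      f_c <- rhs / prec + stats::rnorm(n) / sqrt(prec)
      Fstar[, c] <- f_c
      R <- R - tcrossprod(f_c, lam_c)
    }

    ## 4. factor genetic share on the discrete grid
    for (c in seq_len(k)) {
      ll <- vapply(h2_grid, function(hh) {
        vv <- hh * d + (1 - hh)
        -0.5 * sum(log(vv) + Fstar[, c]^2 / vv)
      }, numeric(1))
      pr <- exp(ll - max(ll))
      h[c] <- h2_grid[sample.int(length(h2_grid), 1, prob = pr)]
    }

    ## 5. loadings with column shrinkage
    FtF <- crossprod(Fstar)
    for (j in seq_len(t_)) {
      prec_j <- FtF / sigma2[j] + diag(tau, k)
      ch <- chol((prec_j + t(prec_j)) / 2)
      rhs <- crossprod(Fstar, Yadj[, j]) / sigma2[j]
      mean_j <- backsolve(ch, forwardsolve(t(ch), rhs))
      Lambda[j, ] <- mean_j + backsolve(ch, stats::rnorm(k))
    }

    ## 6. idiosyncratic genetic effects (vectorized over lines and traits)
    R2 <- Ystar - Fstar %*% t(Lambda)
    dg <- outer(d, sigma2_g)                       # prior variances
    se <- matrix(sigma2, n, t_, byrow = TRUE)
    v_u <- dg * se / (dg + se)
    v_u[dg == 0] <- 0
    Ustar_r <- v_u * R2 / se + sqrt(v_u) * matrix(stats::rnorm(n * t_), n, t_)

    ## 7. variances
    W <- Ustar_r[keep, , drop = FALSE] / sqrt(d[keep])
    sigma2_g <- (nu0 * s0_g + colSums(W^2)) / stats::rchisq(t_, nu0 + r_eff)
    E <- R2 - Ustar_r
    sigma2 <- (nu0 * s0_e + colSums(E^2)) / stats::rchisq(t_, nu0 + n)

    if (it > burn_in && ((it - burn_in - 1) %% thin == 0)) {
      n_samp <- n_samp + 1L
      mu_sum <- mu_sum + mu
      L_sum <- L_sum + Lambda
      h_sum <- h_sum + h
      s2_sum <- s2_sum + sigma2
      s2g_sum <- s2g_sum + sigma2_g
      FL <- Fstar %*% t(Lambda) + Ustar_r
      Yhat_sum <- Yhat_sum + sweep(U %*% FL, 2, mu, `+`)
      # genetic part of each factor: E[g_ic | f_ic] = h d / (h d + 1 - h)
      num <- outer(d, h)
      shr <- num / sweep(num, 2, 1 - h, `+`)
      shr[!is.finite(shr)] <- 0
      Ugen_sum <- Ugen_sum +
        U %*% ((shr * Fstar) %*% t(Lambda) + Ustar_r)
      G0_sum <- G0_sum + Lambda %*% (h * t(Lambda)) + diag(sigma2_g, t_)
      R0_sum <- R0_sum + Lambda %*% ((1 - h) * t(Lambda)) + diag(sigma2, t_)
    }
  }

  Yhat <- Yhat_sum / n_samp
  dimnames(Yhat) <- dimnames(Y)
  Ugen <- Ugen_sum / n_samp
  dimnames(Ugen) <- dimnames(Y)
  structure(list(mu = mu_sum / n_samp,
                 loadings = L_sum / n_samp,
                 factor_h2 = h_sum / n_samp,
                 sigma2 = s2_sum / n_samp,
                 sigma2_g = s2g_sum / n_samp,
                 Yhat = Yhat,
                 U_gen = Ugen,
                 implied_G0 = G0_sum / n_samp,
                 implied_R0 = R0_sum / n_samp,
                 missing = miss,
                 Y = Y, K = K, k = k,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_samples = n_samp),
            class = "factor_model_fit")
}

#' @export
predict_masked.factor_model_fit <- function(fit, mask) {
  idx <- resolve_mask(fit, mask)
  if (is.null(idx)) return(data.frame(line_id = character(),
                                      trait = character(),
                                      prediction = numeric()))
  observed <- !fit$missing[idx]
  if (any(observed)) {
    Y2 <- fit$Y
    Y2[idx] <- NA
    fit <- fit_factor_model(Y2, fit$K, k = fit$k, n_iter = fit$n_iter,
                            burn_in = fit$burn_in, thin = fit$thin,
                            seed = fit$seed)
  }
  data.frame(line_id = mask$line_id, trait = mask$trait,
             prediction = fit$Yhat[idx])
}
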