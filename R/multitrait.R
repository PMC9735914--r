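# Bayesian multi-trait genomic mixed models fitted by Gibbs sampling with
# missing-data augmentation.
#
# Model: Y (n lines x t traits) = 1 mu' + u + e, with
#   vec(u) ~ N(0, G0 (x) K)  and  vec(e) ~ N(0, R0 (x) I).
# "Traits" may be actual traits, environments, populations (DH vs haploid)
# or any compound of these; the two-trait case is the bivariate DH/haploid
# model and the multi-environment models are the same sampler with one
# column per environment.
#
# The sampler eigendecomposes K once (K = U D U'); in the rotated basis the
# genetic-effect update factorizes over lines after a simultaneous
# diagonalization of (G0, R0), so each sweep is a handful of dense
# matrix products. G0/R0 are updated from inverse-Wishart (UN),
# scaled-inverse-chi-square (D) or factor-analytic (FA) full conditionals;
# missing cells of Y are sampled each sweep (data augmentation), which
# makes CV2-style prediction a by-product of fitting.

#' Covariance structure specification
#'
#' @param genetic one of `"D"`, `"UN"`, `"FA"` for the genetic covariance.
#' @param residual one of `"D"`, `"UN"` for the residual covariance.
#' @param k number of factors when `genetic = "FA"` (must satisfy
#'   `1 <= k < n_traits`).
#' @return a `cov_structure` list.
#' @export
cov_structure <- function(genetic = c("UN", "D", "FA"),
                          residual = c("UN", "D"), k = 1L) {
  genetic <- match.arg(genetic)
  residual <- match.arg(residual)
  stop_if_not(k >= 1, "k must be >= 1")
  structure(list(genetic = genetic, residual = residual, k = as.integer(k)),
            class = "cov_structure")
}

# Parse "UN-UN", "D-D", "FA-D", ... into a cov_structure.
parse_structure <- function(s, k = 1L) {
  parts <- strsplit(toupper(s), "-", fixed = TRUE)[[1]]
  stop_if_not(length(parts) == 2, "structure must look like 'UN-D'")
  cov_structure(genetic = parts[1], residual = parts[2], k = k)
}

# Factor-analytic conditional update on W (r x t, rows iid N(0, G)).
# Returns new Gamma, psi and the implied G = Gamma Gamma' + diag(psi).
fa_update <- function(W, Gamma, psi, tau, nu_psi, s0_psi) {
  r <- nrow(W); t_ <- ncol(W); k <- ncol(Gamma)
  Psi_inv_G <- Gamma / psi
  prec <- diag(k) + crossprod(Gamma, Psi_inv_G)
  C <- chol2inv(chol((prec + t(prec)) / 2))
  Mn <- W %*% Psi_inv_G %*% C
  Sc <- Mn + matrix(stats::rnorm(r * k), r, k) %*% chol((C + t(C)) / 2)
  StS <- crossprod(Sc)
  for (j in seq_len(t_)) {
    prec_j <- StS / psi[j] + diag(tau, k)
    ch <- chol((prec_j + t(prec_j)) / 2)
    rhs <- crossprod(Sc, W[, j]) / psi[j]
    mean_j <- backsolve(ch, forwardsolve(t(ch), rhs))
    Gamma[j, ] <- mean_j + backsolve(ch, stats::rnorm(k))
  }
  resid <- W - Sc %*% t(Gamma)
  ss <- colSums(resid^2)
  psi <- (nu_psi * s0_psi + ss) / stats::rchisq(t_, nu_psi + r)
  list(Gamma = Gamma, psi = psi,
       G = tcrossprod(Gamma) + diag(psi, t_))
}

#' Fit a multi-trait genomic mixed model by Gibbs sampling
#'
#' @param Y n x t numeric matrix of line-level phenotypes; `NA` cells are
#'   sampled by data augmentation and their posterior predictive means are
#'   returned in `Yhat`.
#' @param K GRM (a `grm` or plain PSD matrix) aligned to the rows of `Y`.
#' @param spec a [cov_structure()] or a string such as `"UN-UN"`, `"D-D"`,
#'   `"FA-D"`.
#' @param n_iter,burn_in chain length and burn-in (defaults 20000 / 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 5).
#' @param seed integer seed; the chain is fully reproducible from it.
#' @param k factors when the genetic structure is FA and `spec` is given as
#'   a string.
#' @param keep_samples store thinned G0/R0 draws (default TRUE).
#' @details Priors (weakly informative): inverse-Wishart with
#'   `nu = t + 2` and scale `0.5 * diag(var(Y))` for unstructured blocks;
#'   scaled-inverse-chi-square with df 5 and scale half the trait variance
#'   for diagonal variances; flat on the per-trait intercepts; independent
#'   normals with column-wise geometrically increasing precision
#'   (`2^(c-1)`) on FA loadings.
#' @return a `multitrait_fit`: `mu`, `U_hat` (n x t posterior-mean genetic
#'   effects), `G0_hat`, `R0_hat`, `Yhat` (`1 mu' + U_hat`), `samples`
#'   (thinned G0/R0 draws), `missing` (the augmented cells), and the call
#'   ingredients needed to refit.
#' @export
fit_multitrait <- function(Y, K, spec = "UN-UN",
                           n_iter = 20000, burn_in = 5000, thin = 5,
                           seed = 1L, k = 1L, keep_samples = TRUE) {
  if (is.character(spec)) spec <- parse_structure(spec, k = k)
  stopifnot(inherits(spec, "cov_structure"))
  if (inherits(K, "grm")) K <- K$matrix
  Y <- as.matrix(Y)
  n <- nrow(Y); t_ <- ncol(Y)
  stop_if_not(t_ >= 2, "need >= 2 traits")
  stop_if_not(nrow(K) == n, "K must align with rows of Y")
  stop_if_not(all(colSums(!is.na(Y)) >= 3),
              "every trait must be observed on >= 3 lines")
  stop_if_not(n_iter > burn_in, "chain too short: n_iter must exceed burn_in")
  if (spec$genetic == "FA")
    stop_if_not(spec$k < t_, "FA requires k < number of traits")
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("T%02d", seq_len(t_))
  if (is.null(rownames(Y))) rownames(Y) <- rownames(K) %||%
      sprintf("L%03d", seq_len(n))

  set.seed(seed)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  keep <- d > 1e-8 * max(d, 1e-12)
  d[!keep] <- 0
  U <- eK$vectors
  r_eff <- sum(keep)

  vY <- apply(Y, 2, stats::var, na.rm = TRUE)
  vY[!is.finite(vY) | vY <= 0] <- 1e-6
  nu_un <- t_ + 2
  S0 <- diag(0.5 * vY, t_)
  nu_d <- 5
  s0_d <- 0.5 * vY
  nu_psi <- 5
  s0_psi <- 0.05 * vY

  mu <- colMeans(Y, na.rm = TRUE)
  miss <- is.na(Y)
  Ycur <- Y
  Ycur[miss] <- matrix(mu, n, t_, byrow = TRUE)[miss]
  u <- matrix(0, n, t_)
  # warm-start the genetic/residual split from per-trait spectral REML;
  # a flat 50:50 split mixes slowly when a trait is near-degenerate
  h2_init <- vapply(seq_len(t_), function(j) {
    tryCatch(min(max(fit_gblup(Y[, j], K)$h2, 0.05), 0.95),
             error = function(e) 0.5)
  }, numeric(1))
  G0 <- diag(h2_init * vY, t_)
  R0 <- diag((1 - h2_init) * vY, t_)
  Gamma <- matrix(stats::rnorm(t_ * spec$k, 0, 0.1), t_, spec$k)
  psi <- 0.5 * vY
  tau <- 2^(seq_len(spec$k) - 1)

  pat_key <- apply(miss, 1, function(x) paste(as.integer(x), collapse = ""))
  pat_groups <- split(seq_len(n), pat_key)
  pat_groups <- pat_groups[vapply(names(pat_groups),
                                  function(s) grepl("1", s), TRUE)]

  mu_sum <- numeric(t_); U_sum <- matrix(0, n, t_)
  G0_sum <- matrix(0, t_, t_); R0_sum <- matrix(0, t_, t_)
  G0_draws <- list(); R0_draws <- list()
  n_samp <- 0L

  for (it in seq_len(n_iter)) {
    ## 1. impute missing cells from the residual conditional
    if (length(pat_groups)) {
      mean_mat <- sweep(u, 2, mu, `+`)
      for (g in pat_groups) {
        Mset <- which(miss[g[1], ])
        Oset <- which(!miss[g[1], ])
        ng <- length(g)
        if (length(Oset) == 0) {
          Ycur[g, Mset] <- mean_mat[g, Mset, drop = FALSE] +
            rmat_norm_rows(ng, R0[Mset, Mset, drop = FALSE])
        } else {
          Roo_inv <- chol2inv(chol(R0[Oset, Oset, drop = FALSE]))
          B <- R0[Mset, Oset, drop = FALSE] %*% Roo_inv
          cond_cov <- R0[Mset, Mset, drop = FALSE] -
            B %*% R0[Oset, Mset, drop = FALSE]
          e_obs <- Ycur[g, Oset, drop = FALSE] - mean_mat[g, Oset, drop = FALSE]
          cmean <- e_obs %*% t(B)
          Ycur[g, Mset] <- mean_mat[g, Mset, drop = FALSE] + cmean +
            rmat_norm_rows(ng, (cond_cov + t(cond_cov)) / 2)
        }
      }
    }

    ## 2. intercepts (flat prior)
    mu <- colMeans(Ycur - u) + drop(rmat_norm_rows(1, R0 / n))

    ## 3. genetic effects via simultaneous diagonalization of (G0, R0)
    Yc <- sweep(Ycur, 2, mu)
    Ystar <- crossprod(U, Yc)
    S <- t(chol(R0))
    A1 <- forwardsolve(S, G0)
    Mmat <- forwardsolve(S, t(A1))
    em <- eigen((Mmat + t(Mmat)) / 2, symmetric = TRUE)
    lam <- pmax(em$values, 0)
    Tm <- S %*% em$vectors
    Ytil <- Ystar %*% t(solve(Tm))
    dl <- outer(d, lam)
    v <- dl / (dl + 1)
    util <- v * Ytil + sqrt(v) * matrix(stats::rnorm(n * t_), n, t_)
    ustar <- util %*% t(Tm)
    u <- U %*% ustar

    ## 4. genetic covariance
    W <- ustar[keep, , drop = FALSE] / sqrt(d[keep])
    if (spec$genetic == "UN") {
      G0 <- rinvwishart(nu_un + r_eff, S0 + crossprod(W))
    } else if (spec$genetic == "D") {
      ss <- colSums(W^2)
      G0 <- diag((nu_d * s0_d + ss) / stats::rchisq(t_, nu_d + r_eff), t_)
    } else {
      fa <- fa_update(W, Gamma, psi, tau, nu_psi, s0_psi)
      Gamma <- fa$Gamma; psi <- fa$psi; G0 <- fa$G
    }

    ## 5. residual covariance
    E <- Yc - u
    if (spec$residual == "UN") {
      R0 <- rinvwishart(nu_un + n, S0 + crossprod(E))
    } else {
      ss <- colSums(E^2)
      R0 <- diag((nu_d * s0_d + ss) / stats::rchisq(t_, nu_d + n), t_)
    }

    if (it > burn_in && ((it - burn_in - 1) %% thin == 0)) {
      n_samp <- n_samp + 1L
      mu_sum <- mu_sum + mu
      U_sum <- U_sum + u
      G0_sum <- G0_sum + G0
      R0_sum <- R0_sum + R0
      if (keep_samples) {
        G0_draws[[n_samp]] <- G0
        R0_draws[[n_samp]] <- R0
      }
    }
  }

  mu_hat <- mu_sum / n_samp
  U_hat <- U_sum / n_samp
  dimnames(U_hat) <- dimnames(Y)
  G0_hat <- G0_sum / n_samp
  R0_hat <- R0_sum / n_samp
  dimnames(G0_hat) <- dimnames(R0_hat) <- list(colnames(Y), colnames(Y))
  Yhat <- sweep(U_hat, 2, mu_hat, `+`)
  structure(list(mu = mu_hat, U_hat = U_hat,
                 G0_hat = G0_hat, R0_hat = R0_hat,
                 Yhat = Yhat,
                 samples = if (keep_samples)
                   list(G0 = G0_draws, R0 = R0_draws) else NULL,
                 missing = miss,
                 Y = Y, K = K, spec = spec,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_samples = n_samp),
            class = "multitrait_fit")
}

#' Bivariate DH/haploid genetic-correlation model
#'
#' The two-trait instantiation of the multi-trait model: the same trait
#' measured in the DH population and in its haploid counterparts, sharing
#' the genotype-derived GRM. Missing values are median-substituted per
#' population before fitting (standard practice for these panels), and the
#' unstructured-by-unstructured fit hands its 2 x 2 G0/R0 to the
#' correlation estimators.
#'
#' @param y_D,y_H numeric vectors over the same line set (DH and haploid
#'   phenotypes); NA allowed.
#' @param K GRM shared by the populations.
#' @param ... passed to [fit_multitrait()] (chain lengths, seed).
#' @return a `multitrait_fit` with extra elements `rG`, `rP`, `h2_D`,
#'   `h2_H` and `varcomp` (a [var_comp_pair()]).
#' @export
fit_bivariate_dh_hap <- function(y_D, y_H, K, ...) {
  stop_if_not(length(y_D) == length(y_H), "y_D and y_H must align")
  n_complete <- sum(!is.na(y_D) & !is.na(y_H))
  if (n_complete < 30)
    warning("fewer than 30 complete DH/haploid pairs; rG estimate may be unstable",
            call. = FALSE)
  y_D[is.na(y_D)] <- stats::median(y_D, na.rm = TRUE)
  y_H[is.na(y_H)] <- stats::median(y_H, na.rm = TRUE)
  fit <- fit_multitrait(cbind(DH = y_D, HAP = y_H), K, spec = "UN-UN", ...)
  v <- var_comp_pair(sigma_G_DH = fit$G0_hat[1, 2],
                     sigma2_G_D = fit$G0_hat[1, 1],
                     sigma2_G_H = fit$G0_hat[2, 2],
                     sigma2_e_D = fit$R0_hat[1, 1],
                     sigma2_e_H = fit$R0_hat[2, 2])
  fit$varcomp <- v
  fit$rG <- genetic_correlation(v)
  fit$rP <- phenotypic_correlation(v)
  fit$h2_D <- heritability(v$sigma2_G_D, v$sigma2_e_D)
  fit$h2_H <- heritability(v$sigma2_G_H, v$sigma2_e_H)
  fit
}

#' Predictions at masked cells
#'
#' Returns one prediction per masked cell (`X b + u` posterior marginal
#' means). Cells that were observed during fitting trigger a refit with
#' those cells masked, so a prediction never uses the cell's own observed
#' value.
#'
#' @param fit a `multitrait_fit` or `factor_model_fit`.
#' @param mask data.frame with columns `line_id`, `trait` addressing cells
#'   of the fitted Y.
#' @return data.frame `line_id`, `trait`, `prediction`.
#' @export
predict_masked <- function(fit, mask) {
  UseMethod("predict_masked")
}

resolve_mask <- function(fit, mask) {
  if (nrow(mask) == 0) return(NULL)
  ri <- match(mask$line_id, rownames(fit$Y))
  ci <- match(mask$trait, colnames(fit$Y))
  stop_if_not(!anyNA(ri) && !anyNA(ci),
              "mask addresses lines or traits unknown to the fit")
  cbind(ri, ci)
}

#' @export
predict_masked.multitrait_fit <- function(fit, mask) {
  idx <- resolve_mask(fit, mask)
  if (is.null(idx)) return(data.frame(line_id = character(),
                                      trait = character(),
                                      prediction = numeric()))
  observed <- !fit$missing[idx]
  if (any(observed)) {
    Y2 <- fit$Y
    Y2[idx] <- NA
    fit <- fit_multitrait(Y2, fit$K, spec = fit$spec,
                          n_iter = fit$n_iter, burn_in = fit$burn_in,
                          thin = fit$thin, seed = fit$seed,
                          keep_samples = FALSE)
  }
  data.frame(line_id = mask$line_id, trait = mask$trait,
             prediction = fit$Yhat[idx])
}
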