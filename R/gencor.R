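# Correlation and heritability estimators built on fitted variance
# components.

#' Variance-component pair for a trait in the DH and haploid populations
#'
#' @param sigma_G_DH genetic covariance between the populations.
#' @param sigma2_G_D,sigma2_G_H genetic variances.
#' @param sigma2_e_D,sigma2_e_H residual variances.
#' @param sigma_e_DH residual covariance; zero by design because the two
#'   populations grow in different, independently randomized blocks.
#' @return a `var_comp_pair` list.
#' @export
var_comp_pair <- function(sigma_G_DH, sigma2_G_D, sigma2_G_H,
                          sigma2_e_D, sigma2_e_H, sigma_e_DH = 0) {
  stop_if_not(sigma2_G_D >= 0 && sigma2_G_H >= 0 &&
                sigma2_e_D >= 0 && sigma2_e_H >= 0,
              "variances must be non-negative")
  structure(list(sigma_G_DH = sigma_G_DH,
                 sigma2_G_D = sigma2_G_D, sigma2_G_H = sigma2_G_H,
                 sigma2_e_D = sigma2_e_D, sigma2_e_H = sigma2_e_H,
                 sigma_e_DH = sigma_e_DH),
            class = "var_comp_pair")
}

#' Genetic correlation between the DH and haploid populations
#'
#' rG = sigma_G(D,H) / sqrt(sigma2_G(D) * sigma2_G(H)), computed from
#' posterior-mean variance components (plug-in) and clipped to `[-1, 1]`
#' since Monte Carlo noise can breach the bound.
#'
#' @param v a [var_comp_pair()].
#' @return scalar rG.
#' @export
genetic_correlation <- function(v) {
  stopifnot(inherits(v, "var_comp_pair"))
  stop_if_not(v$sigma2_G_D > 0 && v$sigma2_G_H > 0,
              "genetic correlation undefined: zero genetic variance")
  r <- v$sigma_G_DH / sqrt(v$sigma2_G_D * v$sigma2_G_H)
  max(-1, min(1, r))
}

#' Phenotypic correlation between the DH and haploid populations
#'
#' rP = (sigma_G(D,H) + sigma_e(D,H)) /
#'      sqrt((sigma2_G(D)+sigma2_e(D)) * (sigma2_G(H)+sigma2_e(H))),
#' with the residual covariance defaulting to zero (independent blocks).
#'
#' @param v a [var_comp_pair()].
#' @return scalar rP.
#' @export
phenotypic_correlation <- function(v) {
  stopifnot(inherits(v, "var_comp_pair"))
  tot_D <- v$sigma2_G_D + v$sigma2_e_D
  tot_H <- v$sigma2_G_H + v$sigma2_e_H
  stop_if_not(tot_D > 0 && tot_H > 0,
              "phenotypic correlation undefined: zero total variance")
  r <- (v$sigma_G_DH + v$sigma_e_DH) / sqrt(tot_D * tot_H)
  max(-1, min(1, r))
}

#' Narrow-sense heritability from variance components
#'
#' @param sigma2_G additive genetic variance.
#' @param sigma2_e residual variance.
#' @return h2 = sigma2_G / (sigma2_G + sigma2_e).
#' @export
heritability <- function(sigma2_G, sigma2_e) {
  stop_if_not(sigma2_G >= 0 && sigma2_e >= 0, "variances must be >= 0")
  stop_if_not(sigma2_G + sigma2_e > 0,
              "heritability undefined: both variances are zero")
  sigma2_G / (sigma2_G + sigma2_e)
}

#' Posterior summary of rG across thinned G0 draws
#'
#' Alternative to the plug-in estimator: the posterior distribution of the
#' correlation ratio itself, with equal-tail credible interval.
#'
#' @param fit a `multitrait_fit` with stored samples and 2 traits.
#' @param level credible level (default 0.95).
#' @return list with `mean`, `median`, `lower`, `upper`.
#' @export
genetic_correlation_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "multitrait_fit"))
  stop_if_not(!is.null(fit$samples), "fit has no stored samples")
  rs <- vapply(fit$samples$G0, function(G)
    G[1, 2] / sqrt(G[1, 1] * G[2, 2]), numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(rs, c(a, 1 - a), names = FALSE)
  list(mean = mean(rs), median = stats::median(rs),
       lower = q[1], upper = q[2])
}
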