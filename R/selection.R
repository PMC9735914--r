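# Deterministic selection-response theory: direct selection of DH lines
# versus indirect selection on their haploid progenitors.

#' Selection parameters
#'
#' @param i_H,i_D standardized selection intensities in the haploid and DH
#'   populations.
#' @param h_H,h_D square roots of the narrow-sense heritabilities.
#' @param sigma_A_D additive genetic standard deviation in the DH
#'   population.
#' @param r_A additive genetic correlation between the DH and haploid
#'   populations.
#' @return a `selection_params` list.
#' @export
selection_params <- function(i_H = 1, i_D = 1, h_H, h_D, sigma_A_D, r_A) {
  stop_if_not(h_H >= 0 && h_H <= 1 && h_D >= 0 && h_D <= 1,
              "h values must lie in [0, 1]")
  stop_if_not(sigma_A_D >= 0, "sigma_A_D must be >= 0")
  stop_if_not(abs(r_A) <= 1, "|r_A| must be <= 1")
  structure(list(i_H = i_H, i_D = i_D, h_H = h_H, h_D = h_D,
                 sigma_A_D = sigma_A_D, r_A = r_A),
            class = "selection_params")
}

#' Expected DH-level gain from indirect selection on haploids
#'
#' R_D = i_H * r_A(D,H) * h_H * sigma_A(D).
#'
#' @param p a [selection_params()].
#' @return scalar expected response.
#' @export
indirect_response <- function(p) {
  stopifnot(inherits(p, "selection_params"))
  p$i_H * p$r_A * p$h_H * p$sigma_A_D
}

#' Expected DH-level gain from direct selection
#'
#' R_D = i_D * h_D * sigma_A(D).
#'
#' @param p a [selection_params()].
#' @return scalar expected response.
#' @export
direct_response <- function(p) {
  stopifnot(inherits(p, "selection_params"))
  p$i_D * p$h_D * p$sigma_A_D
}

#' Relative efficiency of indirect vs direct selection
#'
#' RE = r_A * h_H / h_D under equal selection intensities; indirect
#' selection is more efficient exactly when r_A * h_H > h_D.
#'
#' @param p a [selection_params()].
#' @return list with `RE` and `verdict` ("indirect_better",
#'   "direct_better" or "tie").
#' @export
relative_efficiency <- function(p) {
  stopifnot(inherits(p, "selection_params"))
  stop_if_not(p$h_D > 0, "relative efficiency undefined when h_D = 0")
  re <- p$r_A * p$h_H / p$h_D
  verdict <- if (re > 1) "indirect_better" else if (re < 1)
    "direct_better" else "tie"
  list(RE = re, verdict = verdict)
}

#' Number of possible hybrid crosses between two heterotic pools
#'
#' @param n_pool1,n_pool2 line counts in the two pools.
#' @return `n_pool1 * n_pool2`.
#' @export
count_hybrid_combinations <- function(n_pool1, n_pool2) {
  stop_if_not(n_pool1 >= 0 && n_pool2 >= 0, "pool sizes must be >= 0")
  n_pool1 * n_pool2
}

#' Selection intensity from a selected fraction
#'
#' Standard truncation-selection helper: for selected fraction alpha,
#' i = dnorm(qnorm(1 - alpha)) / alpha.
#'
#' @param alpha selected fraction in (0, 1).
#' @return standardized selection intensity.
#' @export
selection_intensity <- function(alpha) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stats::dnorm(stats::qnorm(1 - alpha)) / alpha
}

#' Per-trait relative-efficiency table
#'
#' Applies [relative_efficiency()] to a Table-1-shaped correlation table
#' (using rG as the additive correlation and the tabulated heritabilities).
#'
#' @param table data.frame with columns `trait`, `env`, `h2_D`, `h2_H`,
#'   `rG`.
#' @return data.frame with `trait`, `env`, `RE`, `verdict`.
#' @export
selection_efficiency_table <- function(table) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    p <- selection_params(h_H = sqrt(table$h2_H[i]),
                          h_D = sqrt(table$h2_D[i]),
                          sigma_A_D = 1, r_A = table$rG[i])
    re <- relative_efficiency(p)
    data.frame(trait = table$trait[i], env = table$env[i],
               RE = re$RE, verdict = re$verdict)
  })
  do.call(rbind, res)
}
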