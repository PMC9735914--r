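# Multi-trait Gibbs samplers: D/UN/FA covariance structures, the bivariate
# DH/haploid model, the factor model and masked-cell prediction.

test_that("D-D reduces to independent univariate GBLUP fits", {
  p <- small_panel()
  K <- p$K$matrix
  pan <- simulate_trait_panel(K, h2 = c(0.4, 0.5, 0.3),
                              rho = c(0.5, 0.6, 0.4), seed = 7)
  mf <- fit_multitrait(pan$Y, K, spec = "D-D", n_iter = 1500,
                       burn_in = 500, seed = 3)
  for (j in 1:3) {
    g <- fit_gblup(pan$Y[, j], K)
    expect_gt(cor(mf$U_hat[, j], g$u_hat), 0.98)
  }
})

test_that("UN-UN recovers a generating genetic correlation", {
  p <- study_panel()
  K <- p$K$matrix
  pair <- simulate_dh_hap_pair(K, 0.5, 0.5, 0.7, seed = 91)
  f <- fit_multitrait(pair$Y, K, spec = "UN-UN", n_iter = 1500,
                      burn_in = 500, seed = 4)
  rg <- f$G0_hat[1, 2] / sqrt(f$G0_hat[1, 1] * f$G0_hat[2, 2])
  expect_lt(abs(rg - 0.7), 0.15)

  # all sampled and posterior-mean covariance matrices PSD
  min_ev <- min(vapply(c(f$samples$G0, f$samples$R0), function(M)
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
    numeric(1)))
  expect_gt(min_ev, 0)
  expect_gt(min(eigen(f$G0_hat, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("UN fit on diagonal-truth data shrinks off-diagonals", {
  p <- study_panel()
  K <- p$K$matrix
  pan0 <- simulate_trait_panel(K, h2 = c(0.4, 0.4), rho = c(0, 0),
                               rho_e = 0, seed = 8)
  f0 <- fit_multitrait(pan0$Y, K, spec = "UN-UN", n_iter = 1500,
                       burn_in = 500, seed = 4)
  rho_hat <- f0$G0_hat[1, 2] / sqrt(f0$G0_hat[1, 1] * f0$G0_hat[2, 2])
  expect_lt(abs(rho_hat), 0.2)
})

test_that("FA with one factor recovers a rank-1 genetic covariance", {
  p <- study_panel()
  K <- p$K$matrix
  G0r1 <- 0.7 * tcrossprod(c(1, 1))
  set.seed(11)
  u <- dhpredict:::sym_sqrt(K) %*% dhpredict:::rmat_norm_rows(nrow(K), G0r1)
  Y <- u + dhpredict:::rmat_norm_rows(nrow(K), diag(0.3, 2))
  fa <- fit_multitrait(Y, K, spec = "FA-D", k = 1, n_iter = 2500,
                       burn_in = 1000, seed = 6)
  corr <- fa$G0_hat[1, 2] / sqrt(fa$G0_hat[1, 1] * fa$G0_hat[2, 2])
  expect_lt(abs(corr - 1), 0.1)

  expect_error(fit_multitrait(Y, K, spec = "FA-D", k = 2), "k <")
})

test_that("chains are seed-deterministic and seed-robust", {
  p <- small_panel()
  K <- p$K$matrix
  pan <- simulate_trait_panel(K, h2 = c(0.4, 0.5), rho = c(0.5, 0.5),
                              seed = 9)
  f1 <- fit_multitrait(pan$Y, K, spec = "UN-UN", n_iter = 600,
                       burn_in = 200, seed = 5)
  f2 <- fit_multitrait(pan$Y, K, spec = "UN-UN", n_iter = 600,
                       burn_in = 200, seed = 5)
  expect_identical(f1$G0_hat, f2$G0_hat)
  expect_identical(f1$U_hat, f2$U_hat)

  f3 <- fit_multitrait(pan$Y, K, spec = "UN-UN", n_iter = 1500,
                       burn_in = 500, seed = 6)
  f4 <- fit_multitrait(pan$Y, K, spec = "UN-UN", n_iter = 1500,
                       burn_in = 500, seed = 7)
  expect_lt(max(abs(f3$G0_hat - f4$G0_hat)), 0.15)
})

test_that("the bivariate model is exactly the 2-trait multi-trait model", {
  p <- small_panel()
  K <- p$K$matrix
  pair <- simulate_dh_hap_pair(K, 0.4, 0.35, 0.7, seed = 13)
  y_D <- pair$Y[, 1]; y_H <- pair$Y[, 2]
  b <- fit_bivariate_dh_hap(y_D, y_H, K, n_iter = 800, burn_in = 300,
                            seed = 2)
  m <- fit_multitrait(cbind(DH = y_D, HAP = y_H), K, spec = "UN-UN",
                      n_iter = 800, burn_in = 300, seed = 2)
  expect_identical(b$G0_hat, m$G0_hat)
  expect_identical(b$R0_hat, m$R0_hat)

  # duplicated trait: rG -> 1 (checked on the study-scale panel, where the
  # genetic/residual split is well identified)
  ps <- study_panel()
  pair_hi <- simulate_dh_hap_pair(ps$K$matrix, 0.7, 0.7, 0.7, seed = 19)
  bd <- fit_bivariate_dh_hap(pair_hi$Y[, 1], pair_hi$Y[, 1], ps$K$matrix,
                             n_iter = 1200, burn_in = 400, seed = 3)
  expect_gt(bd$rG, 0.98)

  # independent traits: rG near 0
  pan0 <- simulate_trait_panel(K, h2 = c(0.5, 0.5), rho = c(0, 0),
                               rho_e = 0, seed = 17)
  b0 <- fit_bivariate_dh_hap(pan0$Y[, 1], pan0$Y[, 2], K, n_iter = 1200,
                             burn_in = 400, seed = 4)
  expect_lt(abs(b0$rG), 0.15)

  expect_warning(
    fit_bivariate_dh_hap(c(y_D[1:20], rep(NA, length(y_D) - 20)), y_H, K,
                         n_iter = 400, burn_in = 100, seed = 1),
    "fewer than 30")
})

test_that("factor model exploits shared structure and is deterministic", {
  p <- study_panel()
  K <- p$K$matrix
  sc <- simulate_cv2_scenario(K, n_secondary = 6, n_focal = 4, hap = FALSE,
                              seed = 21)
  set.seed(22)
  test <- sample(rownames(sc$Y_dh), 90)
  Ym <- sc$Y_dh
  Ym[test, sc$focal] <- NA
  ff <- fit_factor_model(Ym, K, k = 4, n_iter = 800, burn_in = 300,
                         thin = 2, seed = 2)
  # masked-cell accuracy beats trait-wise GBLUP under the shared generator
  acc_f <- acc_g <- numeric(length(sc$focal))
  for (i in seq_along(sc$focal)) {
    tr <- sc$focal[i]
    g <- fit_gblup(Ym[, tr], K)
    acc_f[i] <- cor(ff$U_gen[test, tr], sc$u_dh[test, tr])
    acc_g[i] <- cor(g$u_hat[test], sc$u_dh[test, tr])
  }
  expect_gt(mean(acc_f - acc_g), 0)

  ff2 <- fit_factor_model(Ym, K, k = 4, n_iter = 800, burn_in = 300,
                          thin = 2, seed = 2)
  expect_identical(ff$Yhat, ff2$Yhat)

  expect_error(fit_factor_model(Ym, K, k = 20), "exceed")
})

test_that("no shared structure collapses the factor model to trait-wise accuracy", {
  p <- study_panel()
  K <- p$K$matrix
  # independent traits: loadings carry no cross-trait signal
  pan <- simulate_trait_panel(K, h2 = rep(0.4, 6), rho = rep(0, 6),
                              rho_e = 0, seed = 23)
  set.seed(24)
  test <- sample(rownames(pan$Y), 90)
  masked <- c("T04", "T05", "T06")
  Ym <- pan$Y
  Ym[test, masked] <- NA
  ff <- fit_factor_model(Ym, K, k = 3, n_iter = 800, burn_in = 300,
                         thin = 2, seed = 3)
  diffs <- vapply(masked, function(tr) {
    g <- fit_gblup(Ym[, tr], K)
    cor(ff$U_gen[test, tr], pan$u[test, tr]) -
      cor(g$u_hat[test], pan$u[test, tr])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("predict_masked honors masking semantics", {
  p <- small_panel()
  K <- p$K$matrix
  pan <- simulate_trait_panel(K, h2 = c(0.4, 0.5), rho = c(0.5, 0.5),
                              seed = 25)
  Ym <- pan$Y
  Ym[1:5, 1] <- NA
  f <- fit_multitrait(Ym, K, spec = "UN-UN", n_iter = 600, burn_in = 200,
                      seed = 5)

  # empty mask -> empty table
  empty <- predict_masked(f, data.frame(line_id = character(),
                                        trait = character()))
  expect_equal(nrow(empty), 0L)

  # masked cells: predictions equal X B + U at those coordinates
  mask <- data.frame(line_id = rownames(pan$Y)[1:5], trait = "T01")
  pm <- predict_masked(f, mask)
  expect_equal(pm$prediction, unname(f$Yhat[cbind(1:5, 1)]))
  expect_false(anyNA(pm$prediction))

  # observed cell: refit ignores the observed value
  mask_obs <- data.frame(line_id = rownames(pan$Y)[10], trait = "T01")
  pm_obs <- predict_masked(f, mask_obs)
  expect_false(isTRUE(all.equal(pm_obs$prediction, f$Yhat[10, 1])))

  expect_error(predict_masked(f, data.frame(line_id = "nope",
                                            trait = "T01")), "unknown")
})
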