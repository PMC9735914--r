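# Univariate mixed models: plot-level BLUP model and spectral REML GBLUP.

test_that("plot model BLUPs equal the balanced-design shrinkage formula", {
  set.seed(3)
  n <- 80
  u <- rnorm(n)
  rec <- data.frame(line_id = rep(sprintf("L%02d", 1:n), 2),
                    block = rep(c("B1", "B2"), each = n),
                    value = rep(u, 2) + rep(c(-0.3, 0.3), each = n) +
                      rnorm(2 * n, 0, 0.8))
  f <- fit_plot_model(rec)
  ybar <- tapply(rec$value, rec$line_id, mean)
  shrink <- f$sigma2_G / (f$sigma2_G + f$sigma2_e / 2)
  closed <- shrink * (ybar - mean(ybar))
  expect_equal(as.numeric(f$blups[names(closed)]), as.numeric(closed),
               tolerance = 1e-10)
  expect_lt(abs(sum(f$blups)), 1e-8)

  expect_error(fit_plot_model(rec[rec$block == "B1", ]), "blocks")
})

test_that("plot model handles a no-signal dataset and recovers truth", {
  set.seed(4)
  rec0 <- data.frame(line_id = rep(sprintf("L%02d", 1:60), 2),
                     block = rep(c("B1", "B2"), each = 60),
                     value = rnorm(120, 5, 1))
  f0 <- fit_plot_model(rec0)
  expect_lt(f0$sigma2_G, 0.15)
  expect_lt(max(abs(f0$blups)), 0.5)

  # sigma2_G / sigma2_e = 1: median estimate within 10% over 50 sims
  ratios <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    n <- 300
    u <- rnorm(n)
    rec <- data.frame(line_id = rep(sprintf("L%03d", 1:n), 2),
                      block = rep(c("B1", "B2"), each = n),
                      value = rep(u, 2) + rnorm(2 * n))
    f <- fit_plot_model(rec)
    f$sigma2_G / f$sigma2_e
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.1)
})

test_that("GBLUP with K = I matches the iid ridge closed form", {
  set.seed(5)
  n <- 40
  y <- rnorm(n)
  names(y) <- sprintf("L%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  f <- fit_gblup(y, K)
  shrink <- 1 / (1 + f$delta)
  expect_equal(unname(f$u_hat), unname(shrink * (y - mean(y))),
               tolerance = 1e-8)
  expect_equal(f$mu, mean(y), tolerance = 1e-8)
})

test_that("GBLUP REML matches a dense grid search of the likelihood", {
  set.seed(6)
  K6 <- matrix(c(2.0, 1.2, 0.3, 0.3, 0.1, 0.1,
                 1.2, 2.0, 0.3, 0.3, 0.1, 0.1,
                 0.3, 0.3, 2.0, 1.4, 0.2, 0.2,
                 0.3, 0.3, 1.4, 2.0, 0.2, 0.2,
                 0.1, 0.1, 0.2, 0.2, 2.0, 0.9,
                 0.1, 0.1, 0.2, 0.2, 0.9, 2.0), 6, 6)
  y6 <- c(-1.23, -2.51, -0.30, 2.05, 0.72, 2.30)
  f <- fit_gblup(y6, K6)

  # independent restricted-likelihood oracle on (sigma2_g, sigma2_e)
  reml_ll <- function(s2g, s2e) {
    V <- s2g * K6 + s2e * diag(6)
    Vi <- solve(V)
    X <- matrix(1, 6, 1)
    XtVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
    -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
              drop(crossprod(y6, P %*% y6)))
  }
  lo <- c(1e-4, 1e-4); hi <- c(4, 4)
  for (stage in 1:4) {
    gr <- expand.grid(g = seq(lo[1], hi[1], length.out = 41),
                      e = seq(lo[2], hi[2], length.out = 41))
    ll <- mapply(reml_ll, gr$g, gr$e)
    best <- gr[which.max(ll), ]
    step <- c(diff(range(gr$g)), diff(range(gr$e))) / 40
    lo <- pmax(c(best$g, best$e) - 2 * step, 1e-6)
    hi <- c(best$g, best$e) + 2 * step
  }
  expect_lt(abs(f$sigma2_g - best$g) / best$g, 1e-3)
  expect_lt(abs(f$sigma2_e - best$e) / best$e, 1e-3)
})

test_that("GBLUP recovers heritability and is optimal over random ratios", {
  p <- small_panel()
  K <- p$K$matrix
  h2s <- vapply(1:30, function(s) {
    pair <- simulate_dh_hap_pair(K, 0.5, 0.5, 0.7, seed = 400 + s)
    fit_gblup(pair$Y[, 1], K)$h2
  }, numeric(1))
  expect_gt(mean(h2s), 0.4)
  expect_lt(mean(h2s), 0.6)

  # local-optimality audit: returned optimum beats random lambda values
  pair <- simulate_dh_hap_pair(K, 0.5, 0.5, 0.7, seed = 77)
  f <- fit_gblup(pair$Y[, 1], K)
  n <- nrow(K)
  Pc <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(Pc %*% K %*% Pc, symmetric = TRUE)
  xi <- pmax(e$values[1:(n - 1)], 0)
  eta2 <- drop(crossprod(e$vectors[, 1:(n - 1)], pair$Y[, 1]))^2
  set.seed(8)
  lls <- vapply(exp(runif(100, log(1e-6), log(1e6))), function(dl)
    dhpredict:::gblup_profile_reml(dl, xi, eta2), numeric(1))
  expect_true(all(f$loglik_restricted >= lls - 1e-6))
})

test_that("GBLUP is invariant to line reordering and predicts missing lines", {
  p <- small_panel()
  K <- p$K$matrix
  pair <- simulate_dh_hap_pair(K, 0.4, 0.4, 0.7, seed = 31)
  y <- pair$Y[, 1]
  y[1:20] <- NA
  f <- fit_gblup(y, K)
  expect_equal(length(f$u_hat), nrow(K))
  expect_gt(cor(f$u_hat[1:20], pair$u[1:20, 1]), 0.3)

  perm <- sample(nrow(K))
  f2 <- fit_gblup(y[perm], K[perm, perm])
  expect_equal(f2$u_hat[rownames(K)], f$u_hat, tolerance = 1e-6)
  expect_equal(f2$h2, f$h2, tolerance = 1e-6)

  expect_error(fit_gblup(rep(NA_real_, nrow(K)), K), "phenotyped")
})
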