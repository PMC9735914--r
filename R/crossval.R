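# CV2-style cross-validation plans, accuracy metrics and the corrected
# resampled t-test.

#' CV2 plan for a single-environment trial (50:50 by default)
#'
#' Per repeat, a random `fraction` of lines has all focal-trait cells
#' masked; secondary traits stay fully observed for everyone — the CV2
#' scheme where secondary traits of all lines are measured but focal
#' traits of some are not.
#'
#' @param lines character vector of line ids.
#' @param focal_traits,secondary_traits disjoint trait-name sets.
#' @param J number of repeats (default 20).
#' @param fraction fraction of lines masked per repeat, in (0, 1)
#'   (default 0.5).
#' @param seed integer seed.
#' @return a `cv_plan`: list of per-repeat masks (data.frames with
#'   `line_id`, `trait`), plus scheme metadata including the
#'   test:train ratio `rho` used by the corrected t-test.
#' @export
make_cv2_single_env <- function(lines, focal_traits, secondary_traits,
                                J = 20, fraction = 0.5, seed = 1L) {
  stop_if_not(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  stop_if_not(length(intersect(focal_traits, secondary_traits)) == 0,
              "focal and secondary trait sets must be disjoint")
  set.seed(seed)
  n <- length(lines)
  n_mask <- round(fraction * n)
  masks <- lapply(seq_len(J), function(j) {
    test_lines <- sample(lines, n_mask)
    expand.grid(line_id = test_lines, trait = focal_traits,
                stringsAsFactors = FALSE)
  })
  structure(list(masks = masks, J = J, scheme = "single_env_50_50",
                 fraction = fraction,
                 focal_traits = focal_traits,
                 secondary_traits = secondary_traits,
                 rho = fraction / (1 - fraction), seed = seed),
            class = "cv_plan")
}

#' CV2 plan for multi-environment trials (20% per environment)
#'
#' Per repeat and per environment, `fraction` of lines' cells are masked
#' independently. The same plan must be reused across all models compared.
#'
#' @param lines line ids.
#' @param envs environment names (each a "trait" column of the stacked Y).
#' @param J repeats (default 20).
#' @param fraction masked fraction per environment (default 0.2).
#' @param seed integer seed.
#' @return a `cv_plan` with per-repeat masks (`line_id`, `trait` = env).
#' @export
make_cv2_multi_env <- function(lines, envs, J = 20, fraction = 0.2,
                               seed = 1L) {
  stop_if_not(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  set.seed(seed)
  n <- length(lines)
  n_mask <- round(fraction * n)
  masks <- lapply(seq_len(J), function(j) {
    do.call(rbind, lapply(envs, function(e) {
      data.frame(line_id = sample(lines, n_mask), trait = e)
    }))
  })
  structure(list(masks = masks, J = J, scheme = "multi_env_20pct",
                 fraction = fraction, envs = envs,
                 rho = fraction / (1 - fraction), seed = seed),
            class = "cv_plan")
}

#' Prediction accuracy as cor(y, a-hat)
#'
#' Pearson correlation between observed values and predictions over masked
#' cells (pooled across environments in multi-environment schemes).
#'
#' @param predictions,observed aligned numeric vectors over masked cells.
#' @return scalar correlation, or `NA` (flagged with a warning) when either
#'   vector has zero variance.
#' @export
accuracy_cor_y <- function(predictions, observed) {
  ok <- !is.na(predictions) & !is.na(observed)
  stop_if_not(sum(ok) >= 3, "need >= 3 masked cells with both values")
  p <- predictions[ok]; o <- observed[ok]
  if (stats::sd(p) == 0 || stats::sd(o) == 0) {
    warning("zero variance in predictions or observations; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(p, o)
}

#' Genetic prediction accuracy cor(a, a-hat)
#'
#' Because focal and secondary traits share plot-level non-genetic
#' variation, raw cor(y, a-hat) is biased for the accuracy on breeding
#' values. Following the estimated-genetic-correlation approach, a
#' bivariate genomic model is fitted to (y, u-hat) on the test lines and
#' the accuracy is the estimated genetic correlation between them times
#' the square root of the estimated heritability of u-hat, clipped to
#' `[-1, 1]`.
#'
#' @param u_hat predicted genetic values on test lines.
#' @param y observed phenotypes on test lines.
#' @param K GRM restricted to (or covering) the test lines; rows are
#'   matched by the names of `u_hat`.
#' @param n_iter,burn_in short-chain defaults (800 / 300) — the estimator
#'   is evaluated hundreds of times inside cross-validation.
#' @param seed integer seed.
#' @return scalar accuracy, or `NA` (flagged) if the bivariate fit fails.
#' @export
accuracy_genetic <- function(u_hat, y, K, n_iter = 800, burn_in = 300,
                             seed = 1L) {
  if (inherits(K, "grm")) K <- K$matrix
  ids <- names(u_hat)
  if (!is.null(ids) && !is.null(rownames(K)) && !all(ids %in% rownames(K)))
    stop("u_hat names not found in K", call. = FALSE)
  if (!is.null(ids) && !is.null(rownames(K)))
    K <- K[ids, ids, drop = FALSE]
  if (length(u_hat) < 30)
    warning("fewer than 30 test lines; genetic accuracy may be unstable",
            call. = FALSE)
  res <- tryCatch({
    # genetic correlation from the bivariate Gibbs fit; heritability of
    # u_hat from spectral REML (no prior floor on a near-noiseless trait)
    fit <- fit_multitrait(cbind(y = y, u_hat = u_hat), K, spec = "UN-UN",
                          n_iter = n_iter, burn_in = burn_in, thin = 2,
                          seed = seed, keep_samples = FALSE)
    g <- fit$G0_hat
    rg <- g[1, 2] / sqrt(g[1, 1] * g[2, 2])
    h2_u <- fit_gblup(u_hat, K)$h2
    max(-1, min(1, rg * sqrt(h2_u)))
  }, error = function(e) {
    warning("bivariate accuracy fit failed: ", conditionMessage(e),
            call. = FALSE)
    NA_real_
  })
  res
}

#' Corrected resampled t-test for paired cross-validation accuracies
#'
#' Repeated cross-validation runs share training data, so the per-repeat
#' accuracy differences are positively correlated and the naive paired
#' t-test is anti-conservative. The corrected test inflates the variance
#' by `(1/J + n_test/n_train)` (Nadeau-Bengio correction).
#'
#' @param acc_a,acc_b equal-length accuracy vectors over the J repeats.
#' @param n_train,n_test training and testing set sizes of the scheme.
#' @return a `ttest_result`: `mean_diff`, `var_diff`, `J`, `rho`, `t_stat`,
#'   `p_value` (two-sided, t with J - 1 df), `naive_t`, `naive_p`.
#' @export
corrected_resampled_ttest <- function(acc_a, acc_b, n_train, n_test) {
  stop_if_not(length(acc_a) == length(acc_b),
              "accuracy vectors must have equal length")
  J <- length(acc_a)
  stop_if_not(J >= 2, "need J >= 2 repeats")
  d <- acc_a - acc_b
  dbar <- mean(d)
  s2 <- stats::var(d)
  rho <- n_test / n_train
  if (s2 == 0) {
    t_stat <- if (dbar == 0) 0 else sign(dbar) * Inf
    naive_t <- t_stat
  } else {
    t_stat <- dbar / sqrt((1 / J + rho) * s2)
    naive_t <- dbar / sqrt(s2 / J)
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df = J - 1)
  naive_p <- if (is.infinite(naive_t)) 0 else
    2 * stats::pt(-abs(naive_t), df = J - 1)
  structure(list(mean_diff = dbar, var_diff = s2, J = J, rho = rho,
                 t_stat = t_stat, p_value = p,
                 naive_t = naive_t, naive_p = naive_p),
            class = "ttest_result")
}

#' Run a CV2 comparison of prediction models on a trait panel
#'
#' For each repeat of `plan`, masks the planned cells, fits each requested
#' model on the masked data, and scores predictions at the masked focal
#' cells. Models: `"gblup"` (univariate per focal trait, trained on the
#' unmasked lines), `"factor"` (the genomic factor model on all traits),
#' or a `multitrait_fit` structure string such as `"UN-UN"`.
#'
#' @param Y n x t line-level phenotype matrix (complete; masking comes from
#'   the plan).
#' @param K GRM.
#' @param plan a `cv_plan` from [make_cv2_single_env()] or
#'   [make_cv2_multi_env()].
#' @param models character vector of model labels.
#' @param metric `"genetic"` (default for single-environment CV2) or
#'   `"cor_y"`.
#' @param n_iter,burn_in chain controls for the Bayesian fits.
#' @param k factors for the factor model / FA structures.
#' @param seed integer seed.
#' @return an `accuracy_table` data.frame: `model`, `trait`, `repeat_id`,
#'   `accuracy`, `metric`.
#' @export
run_cv2 <- function(Y, K, plan, models = c("gblup", "factor"),
                    metric = c("genetic", "cor_y"),
                    n_iter = 2000, burn_in = 500, k = 8, seed = 1L) {
  metric <- match.arg(metric)
  if (inherits(K, "grm")) K <- K$matrix
  stopifnot(inherits(plan, "cv_plan"))
  focal <- plan$focal_traits %||% unique(plan$masks[[1]]$trait)
  rows <- list()
  for (j in seq_len(plan$J)) {
    mask <- plan$masks[[j]]
    Ym <- Y
    ri <- match(mask$line_id, rownames(Y))
    ci <- match(mask$trait, colnames(Y))
    Ym[cbind(ri, ci)] <- NA
    for (model in models) {
      preds <- switch(
        model,
        gblup = {
          out <- Y * NA
          for (tr in focal) {
            f <- fit_gblup(Ym[, tr], K)
            out[, tr] <- f$u_hat
          }
          out
        },
        factor = {
          f <- fit_factor_model(Ym, K, k = min(k, ncol(Y) - 1),
                                n_iter = n_iter, burn_in = burn_in,
                                thin = 2, seed = seed + j)
          # predicted genetic values, not fitted phenotypes: the shared
          # residual factor must not leak into breeding-value predictions
          sweep(f$U_gen, 2, f$mu, `+`)
        },
        {
          f <- fit_multitrait(Ym, K, spec = model, k = min(k, ncol(Y) - 1),
                              n_iter = n_iter, burn_in = burn_in,
                              thin = 2, seed = seed + j,
                              keep_samples = FALSE)
          f$Yhat
        })
      for (tr in focal) {
        cells <- mask[mask$trait == tr, ]
        if (!nrow(cells)) next
        idx <- match(cells$line_id, rownames(Y))
        u_hat <- preds[idx, tr]
        names(u_hat) <- cells$line_id
        obs <- Y[idx, tr]
        acc <- if (metric == "cor_y") {
          accuracy_cor_y(u_hat, obs)
        } else {
          suppressWarnings(
            accuracy_genetic(u_hat, obs, K, seed = seed + 1000L * j))
        }
        rows[[length(rows) + 1]] <- data.frame(
          model = model, trait = tr, repeat_id = j,
          accuracy = acc, metric = metric)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_table", class(out))
  out
}

#' Trait-assisted CV2 benchmark: univariate vs factor model, with and
#' without haploid secondary columns
#'
#' Runs the single-environment CV2 comparison on a
#' [simulate_cv2_scenario()] study: per repeat, a random half of the lines
#' has all focal-trait cells masked; models are scored on those cells with
#' the genetic accuracy estimator. Arms: univariate GBLUP per focal trait
#' (`gblup`), the factor model on all DH traits (`factor_dh`), and
#' optionally the factor model on DH traits plus fully observed haploid
#' columns (`factor_dh_hap`).
#'
#' @param scenario output of [simulate_cv2_scenario()].
#' @param K GRM used for fitting (typically the one the scenario was
#'   generated from).
#' @param J CV repeats (default 20).
#' @param include_hap add the DH+Hap arm (default `!is.null(scenario$Y_hap)`).
#' @param n_iter,burn_in factor-model chain controls (defaults 800 / 300).
#' @param acc_iter,acc_burn chain controls of the bivariate accuracy
#'   estimator (defaults 500 / 200).
#' @param k factors (default 8).
#' @param seed integer seed.
#' @return an `accuracy_table` with models `gblup`, `factor_dh` and
#'   optionally `factor_dh_hap`.
#' @export
run_trait_assisted_benchmark <- function(scenario, K, J = 20,
                                         include_hap = !is.null(scenario$Y_hap),
                                         n_iter = 800, burn_in = 300,
                                         acc_iter = 500, acc_burn = 200,
                                         k = 8, seed = 1L) {
  if (inherits(K, "grm")) K <- K$matrix
  Y <- scenario$Y_dh
  focal <- scenario$focal
  lines <- rownames(Y)
  n <- length(lines)
  set.seed(seed)
  rows <- list()
  for (j in seq_len(J)) {
    test <- sample(lines, round(n / 2))
    Ym <- Y
    Ym[test, focal] <- NA

    preds <- list()
    gb <- matrix(NA_real_, n, length(focal),
                 dimnames = list(lines, focal))
    for (tr in focal) gb[, tr] <- fit_gblup(Ym[, tr], K)$u_hat
    preds$gblup <- gb

    fd <- fit_factor_model(Ym, K, k = k, n_iter = n_iter,
                           burn_in = burn_in, thin = 2, seed = seed + j)
    preds$factor_dh <- fd$U_gen[, focal, drop = FALSE]

    if (include_hap) {
      Yjoint <- cbind(Ym, scenario$Y_hap)
      fh <- fit_factor_model(Yjoint, K, k = k, n_iter = n_iter,
                             burn_in = burn_in, thin = 2,
                             seed = seed + 500L + j)
      preds$factor_dh_hap <- fh$U_gen[, focal, drop = FALSE]
    }

    for (model in names(preds)) {
      for (tr in focal) {
        u_hat <- preds[[model]][test, tr]
        names(u_hat) <- test
        acc <- suppressWarnings(
          accuracy_genetic(u_hat, Y[test, tr], K,
                           n_iter = acc_iter, burn_in = acc_burn,
                           seed = seed + 7L * j))
        rows[[length(rows) + 1]] <- data.frame(
          model = model, trait = tr, repeat_id = j,
          accuracy = acc, metric = "genetic")
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_table", class(out))
  out
}

#' Pairwise corrected t-tests from an accuracy table
#'
#' @param acc an `accuracy_table` from [run_cv2()].
#' @param model_a,model_b model labels to compare (A minus B).
#' @param rho test:train size ratio (e.g. 1 for 50:50, 0.25 for 80:20).
#' @return data.frame with one row per trait: mean difference, t statistic
#'   and two-sided p-value of the corrected test.
#' @export
compare_models <- function(acc, model_a, model_b, rho) {
  traits <- unique(acc$trait)
  res <- lapply(traits, function(tr) {
    a <- acc$accuracy[acc$model == model_a & acc$trait == tr]
    b <- acc$accuracy[acc$model == model_b & acc$trait == tr]
    ok <- !is.na(a) & !is.na(b)
    tt <- corrected_resampled_ttest(a[ok], b[ok], n_train = 1,
                                    n_test = rho)
    data.frame(trait = tr, mean_diff = tt$mean_diff, t_stat = tt$t_stat,
               p_value = tt$p_value, J = tt$J)
  })
  do.call(rbind, res)
}
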