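# End-to-end pipeline driver: simulate -> QC -> GRM -> fits -> CV2 ->
# correlations -> selection -> report.

#' Run the full synthetic-study pipeline
#'
#' Thin driver chaining the package's modules on a simulated study; every
#' artifact is written under `out_dir` (genotypes, map, phenotypes, GRM,
#' QC report, accuracy table, model-comparison table, DH/haploid
#' correlation table, selection-efficiency table, and a log with the seed
#' and package version). Configuration errors (unknown model names,
#' invalid sizes) are raised before any computation starts.
#'
#' @param config list with elements `simulate` (arguments to
#'   [sim_config()]), `qc` (optional [qc_filter()] thresholds), `models`
#'   (labels understood by [run_cv2()]), `crossval` (list: `J`,
#'   `fraction`), `chain` (list: `n_iter`, `burn_in`), `n_secondary`,
#'   `n_focal`, and `seed`.
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  known_models <- c("gblup", "factor", "D-D", "D-UN", "UN-D", "UN-UN",
                    "FA-D", "FA-UN")
  models <- config$models %||% c("gblup", "factor")
  bad <- setdiff(models, known_models)
  stop_if_not(length(bad) == 0, "unknown model name(s): %s",
              paste(bad, collapse = ", "))
  n_sec <- config$n_secondary %||% 4
  n_foc <- config$n_focal %||% 3
  seed <- config$seed %||% 1L
  cv <- config$crossval %||% list(J = 3, fraction = 0.5)
  chain <- config$chain %||% list(n_iter = 600, burn_in = 200)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(sim_config, c(config$simulate %||% list(), list(seed = seed)))

  sim <- simulate_biparental_dh(cfg)
  hap <- derive_haploid_population(sim$geno)
  qc <- do.call(qc_filter, c(list(g = sim$geno), config$qc %||% list()))
  K <- compute_grm(qc$geno)

  t_tot <- n_sec + n_foc
  set.seed(seed)
  panel <- simulate_trait_panel(K$matrix,
                                h2 = stats::runif(t_tot, 0.2, 0.6),
                                rho = stats::runif(t_tot, 0.4, 0.8),
                                seed = seed)
  traits <- panel$traits
  secondary <- traits[seq_len(n_sec)]
  focal <- setdiff(traits, secondary)

  plan <- make_cv2_single_env(rownames(panel$Y), focal, secondary,
                              J = cv$J, fraction = cv$fraction, seed = seed)
  acc <- run_cv2(panel$Y, K$matrix, plan, models = models,
                 metric = "cor_y", n_iter = chain$n_iter,
                 burn_in = chain$burn_in, seed = seed)
  cmp <- if (length(models) >= 2)
    compare_models(acc, models[2], models[1], rho = plan$rho) else NULL

  # DH/haploid genetic correlation for the first focal trait
  pair <- simulate_dh_hap_pair(K$matrix, h2_D = 0.4, h2_H = 0.35,
                               rG = 0.7, seed = seed + 7L)
  biv <- fit_bivariate_dh_hap(pair$Y[, 1], pair$Y[, 2], K$matrix,
                              n_iter = chain$n_iter,
                              burn_in = chain$burn_in, seed = seed)
  cor_tab <- data.frame(trait = focal[1], env = "E1",
                        h2_D = biv$h2_D, h2_H = biv$h2_H,
                        rP = biv$rP, rG = biv$rG)
  sel <- selection_efficiency_table(cor_tab)

  pheno_long <- data.frame(
    line_id = rep(rownames(panel$Y), times = t_tot),
    population = "DH", env = "E1", block = "B1",
    trait = rep(traits, each = nrow(panel$Y)),
    value = as.vector(panel$Y))
  paths <- write_simulated_study(sim$geno, pheno_long, dir = out_dir)
  utils::write.csv(as.data.frame(acc), file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  if (!is.null(cmp))
    utils::write.csv(cmp, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
  utils::write.csv(cor_tab, file.path(out_dir, "dh_hap_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(sel, file.path(out_dir, "selection_efficiency.csv"),
                   row.names = FALSE)
  write_grm_tsv(K, file.path(out_dir, "grm.tsv"))
  writeLines(c(sprintf("dhpredict %s",
                       as.character(utils::packageVersion("dhpredict"))),
               sprintf("seed: %d", seed),
               sprintf("models: %s", paste(models, collapse = ", ")),
               sprintf("qc: %d -> %d markers, %d -> %d lines",
                       qc$report$n_markers_in, qc$report$n_markers_out,
                       qc$report$n_lines_in, qc$report$n_lines_out)),
             file.path(out_dir, "pipeline_log.txt"))
  invisible(list(geno = sim$geno, hap = hap, qc = qc$report, K = K,
                 panel = panel, accuracy = acc, comparison = cmp,
                 correlations = cor_tab, selection = sel))
}
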