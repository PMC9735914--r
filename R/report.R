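# Table-1-style summaries, dispersion comparisons, and the packaged
# correlation table fixture.

#' Load the packaged DH/haploid correlation table
#'
#' Per-trait heritabilities and phenotypic/genotypic correlations between
#' the DH population and its haploid counterparts in two environments
#' (BJ2014, SJZ2014), as published for the 35-trait maize panel.
#'
#' @return data.frame with columns `trait`, `tissue`, `trait_class`, `env`,
#'   `h2_D`, `h2_H`, `rP`, `rG`.
#' @export
load_correlation_table <- function() {
  path <- system.file("extdata", "table1_dh_hap_correlations.csv",
                      package = "dhpredict", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize a column of a correlation table
#'
#' Exact order statistics at the table's printed 2-decimal precision:
#' median is the middle order statistic for odd n, the mean of the two
#' middle values for even n.
#'
#' @param table a correlation table (e.g. [load_correlation_table()]).
#' @param column one of its numeric column names.
#' @param env environment to subset to.
#' @return named numeric vector `c(min, max, median)`.
#' @export
summarize_column <- function(table, column, env) {
  stop_if_not(column %in% names(table), "unknown column '%s'", column)
  x <- table[[column]][table$env == env]
  stop_if_not(length(x) >= 1, "no rows for env '%s'", env)
  c(min = round(min(x), 2), max = round(max(x), 2),
    median = round(stats::median(x), 2))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values numeric vector.
#' @return scalar CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  stop_if_not(m != 0, "CV undefined for zero mean")
  stats::sd(values) / m
}

#' Compare dispersion between DH and haploid populations
#'
#' Computes the coefficient of variation per (trait, population), counts
#' the traits where the haploid CV exceeds the DH CV, runs a paired t-test
#' across traits on the CV differences, and per-trait two-sample t-tests of
#' the population means.
#'
#' @param pheno long phenotype data.frame with `line_id`, `population`,
#'   `trait`, `value` (optionally filtered to one trait class upstream).
#' @param traits optional subset of traits to compare.
#' @return list with `cv_table` (trait, cv_DH, cv_HAP), `n_hap_greater`,
#'   `paired_test` (htest), `mean_tests` (per-trait two-sample t-tests).
#' @export
compare_population_dispersion <- function(pheno, traits = NULL) {
  traits <- traits %||% unique(pheno$trait)
  rows <- list(); mean_tests <- list()
  for (tr in traits) {
    d <- pheno$value[pheno$trait == tr & pheno$population == "DH"]
    h <- pheno$value[pheno$trait == tr & pheno$population == "HAP"]
    if (!length(d) || !length(h)) {
      warning(sprintf("trait '%s' missing in one population; skipped", tr),
              call. = FALSE)
      next
    }
    rows[[tr]] <- data.frame(trait = tr,
                             cv_DH = coefficient_of_variation(d),
                             cv_HAP = coefficient_of_variation(h))
    mean_tests[[tr]] <- stats::t.test(d, h)
  }
  cv <- do.call(rbind, rows)
  rownames(cv) <- NULL
  paired <- if (nrow(cv) >= 2 && stats::sd(cv$cv_HAP - cv$cv_DH) > 0)
    stats::t.test(cv$cv_HAP, cv$cv_DH, paired = TRUE) else NULL
  list(cv_table = cv,
       n_hap_greater = sum(cv$cv_HAP > cv$cv_DH),
       paired_test = paired,
       mean_tests = mean_tests)
}
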