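# Synthetic DH / haploid population generator.

test_that("meiosis follows the Haldane model", {
  cfg <- sim_config(n_lines = 1, chrom_lengths_cM = 150,
                    markers_per_chrom = 150, seed = 1)
  map <- make_marker_map(cfg)
  haps <- list(rbind(rep(1L, 150), rep(0L, 150)))

  # crossover counts over many gametes match Poisson(1.5)
  set.seed(42)
  counts <- vapply(seq_len(4000), function(i) {
    g <- simulate_meiosis_gamete(haps, map)
    attr(g[[1]], "n_crossovers")
  }, numeric(1))
  se <- sqrt(1.5 / length(counts))
  expect_lt(abs(mean(counts) - 1.5), 3 * se)

  # goodness of fit to the Poisson pmf
  tab <- table(factor(pmin(counts, 6), levels = 0:6))
  p <- dpois(0:5, 1.5); p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(as.vector(tab), p = p))
  expect_gt(gof$p.value, 0.001)

  # zero-length chromosome: no recombination possible
  cfg0 <- sim_config(n_lines = 1, chrom_lengths_cM = 0,
                     markers_per_chrom = 10, seed = 1)
  map0 <- make_marker_map(cfg0)
  g0 <- simulate_meiosis_gamete(list(rbind(rep(1L, 10), rep(0L, 10))),
                                map0, seed = 3)
  expect_equal(attr(g0[[1]], "n_crossovers"), 0L)
  expect_true(all(g0[[1]] == 1L) || all(g0[[1]] == 0L))

  # identical parental haplotypes: mosaic is invisible
  gid <- simulate_meiosis_gamete(list(rbind(rep(1L, 150), rep(1L, 150))),
                                 map, seed = 5)
  expect_true(all(gid[[1]] == 1L))

  # unordered map rejected
  bad <- map
  bad$position_bp[2:1] <- bad$position_bp[1:2]
  expect_error(simulate_meiosis_gamete(haps, bad), "not ordered")
})

test_that("DH lines are homozygous with balanced parental contributions", {
  cfg <- sim_config(n_lines = 2000, chrom_lengths_cM = rep(150, 2),
                    markers_per_chrom = rep(40, 2), selfing_fraction = 0,
                    seed = 7)
  sim <- simulate_biparental_dh(cfg)
  expect_true(all(sim$geno$dosages %in% c(0L, 2L)))

  freq <- colMeans(sim$geno$dosages) / 2
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(freq) - 0.5), 3 * se)
  expect_true(all(abs(freq - 0.5) < 4.5 * se))
})

test_that("recurrent selfing adds recombination events", {
  cfg_self <- sim_config(n_lines = 120, chrom_lengths_cM = rep(150, 3),
                         markers_per_chrom = rep(50, 3),
                         selfing_fraction = 1, selfing_generations = 3,
                         seed = 9)
  cfg_f1 <- sim_config(n_lines = 120, chrom_lengths_cM = rep(150, 3),
                       markers_per_chrom = rep(50, 3),
                       selfing_fraction = 0, seed = 9)
  n_switch <- function(sim) {
    mean(count_recombinations(sim$origins)$n_recombinations)
  }
  expect_gt(n_switch(simulate_biparental_dh(cfg_self)),
            n_switch(simulate_biparental_dh(cfg_f1)))
  expect_error(sim_config(selfing_fraction = 1.2), "selfing_fraction")
})

test_that("haploid derivation preserves marker content exactly", {
  p <- small_panel()
  hap <- derive_haploid_population(p$sim$geno)
  expect_identical(hap$dosages, p$sim$geno$dosages)
  expect_equal(hap$population, "HAP")

  het <- p$sim$geno
  het$dosages[1, 1] <- 1L
  expect_error(derive_haploid_population(het), "heterozygous")

  empty <- p$sim$geno
  empty$dosages <- empty$dosages[0, , drop = FALSE]
  empty$line_ids <- character(0)
  expect_equal(nrow(derive_haploid_population(empty)$dosages), 0L)
})

test_that("phenotypes realize the generating variance components", {
  # pure noise: between-line variance of line means matches residual-only
  cfg0 <- sim_config(n_lines = 1000, n_traits = 1, n_blocks = 2,
                     G0 = matrix(0, 1, 1), R0 = matrix(0.6, 1, 1),
                     block_sd = 0, seed = 13)
  K <- diag(1000)
  ph0 <- simulate_phenotypes(K, cfg0)
  lm0 <- tapply(ph0$pheno$value, ph0$pheno$line_id, mean)
  expect_lt(abs(var(lm0) - 0.3), 3 * 0.3 * sqrt(2 / 999))

  # h2 = 0.4 recovered by the ANOVA estimator at n = 2000
  cfg <- sim_config(n_lines = 2000, n_traits = 1, n_blocks = 2,
                    G0 = matrix(0.4, 1, 1), R0 = matrix(0.6, 1, 1),
                    block_sd = 0, seed = 14)
  ph <- simulate_phenotypes(diag(2000), cfg)
  y <- matrix(ph$pheno$value, nrow = 2000)   # lines x blocks
  ms_within <- mean(apply(y, 1, var))
  s2g <- var(rowMeans(y)) - ms_within / 2
  h2 <- s2g / (s2g + ms_within)
  expect_lt(abs(h2 - 0.4), 0.03)

  # determinism: same config, byte-identical records
  ph2 <- simulate_phenotypes(diag(2000), cfg)
  expect_identical(ph$pheno, ph2$pheno)

  expect_error(sim_config(n_traits = 2, G0 = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("simulated breeding-value covariance converges to G0", {
  G0 <- matrix(c(0.5, 0.3, 0.3, 0.5), 2)
  cfg <- sim_config(n_lines = 2000, n_traits = 2, G0 = G0,
                    R0 = diag(0.5, 2), seed = 15)
  ph <- simulate_phenotypes(diag(2000), cfg)
  emp <- cov(ph$u)
  expect_lt(norm(emp - G0, "F") / norm(G0, "F"), 0.10)
})

test_that("study files round-trip through the TSV/CSV writers", {
  p <- small_panel()
  cfg1 <- sim_config(n_lines = 120, chrom_lengths_cM = rep(150, 5),
                     markers_per_chrom = rep(60, 5), seed = 101)
  ph <- simulate_phenotypes(p$K$matrix, cfg1)
  dir <- file.path(tempdir(), "study-roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_simulated_study(p$geno, ph$pheno, dir)
  back <- read_genotype_tsv(file.path(dir, "genotypes.tsv"),
                            file.path(dir, "marker_map.tsv"))
  expect_equal(back$dosages, p$geno$dosages)
  expect_equal(back$map$position_cM, p$geno$map$position_cM)
})
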