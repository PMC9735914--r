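# Synthetic DH / haploid population generator.
#
# The simulator emulates a biparental maize cross: two fully inbred parents,
# an F1, and a doubled-haploid (DH) population obtained by sampling one
# gamete per line and doubling it. A configurable minority of lines goes
# through extra generations of recurrent selfing before the gamete is
# sampled, which inflates their recombination counts. Haploid counterparts
# carry the same gamete genome as their DH line. Phenotypes follow the
# standard multi-trait animal model y = Xb + Zu + e with Cov(u) = G0 (x) K
# and Cov(e) = I (x) R0.

#' Simulation configuration for a synthetic DH study
#'
#' Bundles the genome, population and phenotype-model settings used by
#' [simulate_biparental_dh()] and [simulate_phenotypes()]. Defaults mirror a
#' biparental maize DH panel genotyped on a ~1300-SNP chip: 10 chromosomes
#' of 150 cM, 132 markers each, 187 lines, with 10% of lines derived after
#' 3 extra selfing generations.
#'
#' @param n_lines number of DH lines.
#' @param chrom_lengths_cM numeric vector of chromosome lengths in
#'   centiMorgans.
#' @param markers_per_chrom integer vector, markers on each chromosome.
#' @param selfing_fraction fraction of lines in `[0, 1]` derived from
#'   individuals that went through `selfing_generations` extra rounds of
#'   selfing before gamete sampling.
#' @param selfing_generations integer >= 1, extra selfing rounds for those
#'   lines.
#' @param n_traits,n_envs,n_blocks phenotype layout: traits, environments,
#'   and complete blocks per environment.
#' @param G0 genetic covariance matrix over the trait-by-environment
#'   compound dimension (`n_traits * n_envs`); default
#'   `diag(0.4, n_traits * n_envs)`.
#' @param R0 residual covariance matrix of the same dimension; default
#'   `diag(0.6, ...)`.
#' @param n_qtl_per_trait QTL count used when phenotypes are generated from
#'   an explicit trait architecture.
#' @param block_sd standard deviation of the fixed block shifts.
#' @param seed integer seed; all randomness in the simulator flows from it
#'   (phenotype generation uses `seed + 1` so genotypes and phenotypes can
#'   be re-drawn independently).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 187,
                       chrom_lengths_cM = rep(150, 10),
                       markers_per_chrom = rep(132, 10),
                       selfing_fraction = 0.1,
                       selfing_generations = 3,
                       n_traits = 1,
                       n_envs = 1,
                       n_blocks = 2,
                       G0 = NULL,
                       R0 = NULL,
                       n_qtl_per_trait = 20,
                       block_sd = 0.25,
                       seed = 1L) {
  stop_if_not(n_lines >= 1, "n_lines must be >= 1")
  stop_if_not(length(chrom_lengths_cM) == length(markers_per_chrom),
              "chrom_lengths_cM and markers_per_chrom must have equal length")
  stop_if_not(all(chrom_lengths_cM >= 0), "chromosome lengths must be >= 0")
  stop_if_not(all(markers_per_chrom >= 1), "need >= 1 marker per chromosome")
  stop_if_not(selfing_fraction >= 0 && selfing_fraction <= 1,
              "selfing_fraction must be in [0, 1]")
  stop_if_not(selfing_generations >= 1, "selfing_generations must be >= 1")
  t_total <- n_traits * n_envs
  if (is.null(G0)) G0 <- diag(0.4, t_total)
  if (is.null(R0)) R0 <- diag(0.6, t_total)
  stop_if_not(nrow(G0) == t_total && nrow(R0) == t_total,
              "G0/R0 dimension must equal n_traits * n_envs (%d)", t_total)
  check_cov_matrix(G0, "G0")
  check_cov_matrix(R0, "R0")
  structure(list(n_lines = as.integer(n_lines),
                 chrom_lengths_cM = chrom_lengths_cM,
                 markers_per_chrom = as.integer(markers_per_chrom),
                 selfing_fraction = selfing_fraction,
                 selfing_generations = as.integer(selfing_generations),
                 n_traits = as.integer(n_traits),
                 n_envs = as.integer(n_envs),
                 n_blocks = as.integer(n_blocks),
                 G0 = G0, R0 = R0,
                 n_qtl_per_trait = as.integer(n_qtl_per_trait),
                 block_sd = block_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic marker map for a simulated genome
#'
#' Markers are evenly spaced in genetic distance; physical positions assume
#' 1 Mb per cM. Positions are strictly increasing within a chromosome.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `marker_id`, `chromosome`, `position_bp`,
#'   `position_cM`.
#' @export
make_marker_map <- function(config) {
  maps <- lapply(seq_along(config$chrom_lengths_cM), function(chr) {
    m <- config$markers_per_chrom[chr]
    L <- config$chrom_lengths_cM[chr]
    pos_cM <- if (m == 1) L / 2 else seq(0, L, length.out = m)
    data.frame(marker_id = sprintf("chr%d_m%03d", chr, seq_len(m)),
               chromosome = chr,
               position_bp = as.integer(round(pos_cM * 1e6)) + seq_len(m),
               position_cM = pos_cM)
  })
  do.call(rbind, maps)
}

check_map_sorted <- function(map) {
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, ]
    stop_if_not(all(diff(sub$position_bp) > 0) &&
                  all(diff(sub$position_cM) >= 0),
                "marker map is not ordered on chromosome %s", chr)
  }
  stop_if_not(!anyDuplicated(map$marker_id), "marker_id values must be unique")
  invisible(TRUE)
}

# One meiotic gamete for one chromosome under the Haldane model:
# crossover count ~ Poisson(L/100), breakpoints uniform, no interference.
# `hap` is a 2 x m matrix (the two parental haplotypes), pos_cM the map.
sim_gamete_chrom <- function(hap, pos_cM, L) {
  n_xo <- stats::rpois(1, L / 100)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) {
    g <- hap[start, ]
    attr(g, "n_crossovers") <- 0L
    return(g)
  }
  xo <- sort(stats::runif(n_xo, 0, L))
  phase <- (start - 1L + findInterval(pos_cM, xo)) %% 2L + 1L
  g <- hap[cbind(phase, seq_along(pos_cM))]
  attr(g, "n_crossovers") <- n_xo
  g
}

#' Simulate one meiotic gamete (Haldane map function)
#'
#' Crossover counts per chromosome are Poisson(L/100) with uniform,
#' interference-free breakpoint positions; the returned haplotype is a
#' mosaic of the two parental haplotypes switching at each breakpoint.
#'
#' @param parent_haplotypes list (one element per chromosome) of 2 x m
#'   binary matrices, rows = the individual's two haplotypes, columns in
#'   map order.
#' @param map marker map as from [make_marker_map()].
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so the gamete is reproducible.
#' @return list of per-chromosome haplotype vectors; each carries an
#'   `n_crossovers` attribute.
#' @export
simulate_meiosis_gamete <- function(parent_haplotypes, map, seed = NULL) {
  check_map_sorted(map)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chromosome)
  stop_if_not(length(parent_haplotypes) == length(chroms),
              "parent_haplotypes must have one element per chromosome")
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    sub <- map[map$chromosome == chroms[i], ]
    hap <- parent_haplotypes[[i]]
    stop_if_not(ncol(hap) == nrow(sub),
                "haplotypes not aligned to map on chromosome %s", chroms[i])
    L <- max(sub$position_cM)
    out[[i]] <- sim_gamete_chrom(hap, sub$position_cM, L)
  }
  names(out) <- paste0("chr", chroms)
  out
}

#' Simulate a biparental DH population
#'
#' Two fully inbred parents (P1 carrying allele 1, P2 allele 0 at every
#' marker) are crossed; each DH line is one gamete of the F1 (or of a
#' descendant after `selfing_generations` rounds of selfing, for the first
#' `round(selfing_fraction * n_lines)` lines), doubled to homozygosity.
#' Dosages are therefore 0 or 2 only.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (class `genotype_matrix`: `dosages` n x m matrix,
#'   `line_ids`, `marker_ids`, `map`, `population`), `origins` (class
#'   `origin_matrix`, entries "P1"/"P2"), `selfed` (logical per line) and
#'   `crossovers` (n x n_chrom matrix of true crossover counts of the final
#'   sampled gamete).
#' @export
simulate_biparental_dh <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- make_marker_map(config)
  n_chrom <- length(config$chrom_lengths_cM)
  m_per <- config$markers_per_chrom
  m_total <- sum(m_per)
  n <- config$n_lines

  f1 <- lapply(m_per, function(m) rbind(P1 = rep(1L, m), P2 = rep(0L, m)))
  pos_list <- split(map$position_cM, map$chromosome)
  L_vec <- config$chrom_lengths_cM

  n_selfed <- round(config$selfing_fraction * n)
  selfed <- seq_len(n) <= n_selfed

  dosages <- matrix(NA_integer_, n, m_total)
  crossovers <- matrix(0L, n, n_chrom)
  for (i in seq_len(n)) {
    ind <- f1
    if (selfed[i]) {
      for (g in seq_len(config$selfing_generations)) {
        ind <- lapply(seq_len(n_chrom), function(chr) {
          g1 <- sim_gamete_chrom(ind[[chr]], pos_list[[chr]], L_vec[chr])
          g2 <- sim_gamete_chrom(ind[[chr]], pos_list[[chr]], L_vec[chr])
          rbind(g1, g2)
        })
      }
    }
    gam <- integer(0)
    for (chr in seq_len(n_chrom)) {
      g <- sim_gamete_chrom(ind[[chr]], pos_list[[chr]], L_vec[chr])
      crossovers[i, chr] <- attr(g, "n_crossovers")
      gam <- c(gam, as.integer(g))
    }
    dosages[i, ] <- 2L * gam
  }
  line_ids <- sprintf("DH%03d", seq_len(n))
  dimnames(dosages) <- list(line_ids, map$marker_id)
  geno <- structure(list(dosages = dosages,
                         line_ids = line_ids,
                         marker_ids = map$marker_id,
                         map = map,
                         population = "DH"),
                    class = "genotype_matrix")
  origins <- ifelse(dosages == 2L, "P1", "P2")
  origins <- structure(list(origins = origins,
                            line_ids = line_ids,
                            marker_ids = map$marker_id,
                            map = map),
                       class = "origin_matrix")
  list(geno = geno, origins = origins, selfed = selfed,
       crossovers = crossovers)
}

#' Derive the haploid counterpart population of a DH panel
#'
#' Each DH line is fully homozygous, so it produces a single gamete type;
#' the induced haploid carries exactly that genome (the inducer genome is
#' eliminated). Marker content is therefore identical to the DH line; only
#' the population label changes.
#'
#' @param dh a `genotype_matrix` with dosages in \{0, 2\} only.
#' @return a `genotype_matrix` with `population = "HAP"`.
#' @export
derive_haploid_population <- function(dh) {
  stopifnot(inherits(dh, "genotype_matrix"))
  d <- dh$dosages
  if (any(d == 1L, na.rm = TRUE))
    stop("DH input contains heterozygous calls; the gamete is not unique",
         call. = FALSE)
  hap <- dh
  hap$population <- "HAP"
  hap
}

#' Build a QTL trait architecture
#'
#' Picks `n_qtl_per_trait` markers (shared across traits) and draws additive
#' effects whose between-trait covariance follows `G0`; breeding values are
#' rescaled per trait so their realized variance matches `diag(G0)`.
#'
#' @param geno a `genotype_matrix`.
#' @param config a [sim_config()].
#' @return list with `qtl_markers`, `qtl_effects` (q x t matrix) and the
#'   implied breeding-value matrix `u` (n x t, variance-matched to G0).
#' @export
make_trait_architecture <- function(geno, config) {
  set.seed(config$seed + 2L)
  m <- length(geno$marker_ids)
  t_total <- nrow(config$G0)
  q <- min(config$n_qtl_per_trait, m)
  qtl <- sort(sample.int(m, q))
  W <- scale(geno$dosages[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  B <- rmat_norm_rows(q, config$G0)
  u <- W %*% B
  sds <- apply(u, 2, stats::sd)
  target <- sqrt(diag(config$G0))
  scale_fac <- ifelse(sds > 0, target / sds, 0)
  u <- sweep(u, 2, scale_fac, `*`)
  list(qtl_markers = qtl, qtl_effects = sweep(B, 2, scale_fac, `*`), u = u)
}

#' Simulate plot-level phenotypes under the Kronecker model
#'
#' Breeding values u are drawn with Cov(u) = G0 (x) K (or taken from a QTL
#' architecture) and plot residuals with Cov(e) = I (x) R0; fixed block
#' shifts are drawn once per (environment, block) from N(0, block_sd^2).
#' The compound trait dimension is laid out trait-fastest within
#' environment, i.e. column (e - 1) * n_traits + t of G0 is trait t in
#' environment e.
#'
#' @param K genomic relationship matrix (n x n, PSD) with line ids as
#'   dimnames, or `NULL` together with `arch`.
#' @param config a [sim_config()].
#' @param arch optional output of [make_trait_architecture()]; when given,
#'   its breeding values replace the MVN draw.
#' @param population population label written into the records.
#' @param seed overrides `config$seed + 1`.
#' @return list with `pheno` (long data.frame: `line_id`, `population`,
#'   `env`, `block`, `trait`, `value`), `u` (n x t breeding values), and
#'   `block_effects`.
#' @export
simulate_phenotypes <- function(K, config, arch = NULL,
                                population = "DH", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% (config$seed + 1L))
  t_total <- nrow(config$G0)
  check_cov_matrix(config$G0, "G0")
  check_cov_matrix(config$R0, "R0")
  if (is.null(arch)) {
    stop_if_not(!is.null(K), "either K or arch must be supplied")
    n <- nrow(K)
    Lk <- sym_sqrt(K)
    u <- Lk %*% rmat_norm_rows(n, config$G0)
  } else {
    u <- arch$u
    n <- nrow(u)
  }
  line_ids <- rownames(K) %||% sprintf("DH%03d", seq_len(n))
  traits <- sprintf("T%02d", seq_len(config$n_traits))
  envs <- sprintf("E%d", seq_len(config$n_envs))
  col_env <- rep(envs, each = config$n_traits)
  col_trait <- rep(traits, times = config$n_envs)

  block_effects <- matrix(stats::rnorm(config$n_envs * config$n_blocks,
                                       0, config$block_sd),
                          config$n_envs, config$n_blocks,
                          dimnames = list(envs, paste0("B", seq_len(config$n_blocks))))
  recs <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    E <- rmat_norm_rows(n, config$R0)
    Y <- u + E
    Y <- sweep(Y, 2, block_effects[col_env, b], `+`)
    recs[[b]] <- data.frame(line_id = rep(line_ids, times = t_total),
                            population = population,
                            env = rep(col_env, each = n),
                            block = paste0("B", b),
                            trait = rep(col_trait, each = n),
                            value = as.vector(Y))
  }
  pheno <- do.call(rbind, recs)
  rownames(pheno) <- NULL
  colnames(u) <- paste(col_env, col_trait, sep = ":")
  rownames(u) <- line_ids
  list(pheno = pheno, u = u, block_effects = block_effects)
}

#' Line-level DH/haploid phenotype pair with a target genetic correlation
#'
#' Convenience generator used throughout the correlation analyses: a single
#' trait measured in the DH population and in its haploid counterparts is
#' treated as two correlated traits with genetic covariance
#' `rG * sqrt(h2_D * h2_H)` on a total-variance-1 scale; residuals are
#' uncorrelated between populations (different plots).
#'
#' @param K GRM shared by the two populations (identical genotypes).
#' @param h2_D,h2_H narrow-sense heritabilities of the trait in the DH and
#'   haploid populations.
#' @param rG generating additive genetic correlation.
#' @param seed integer seed.
#' @return list with `Y` (n x 2 matrix, columns `DH`, `HAP`), `u` (true
#'   breeding values), `G0`, `R0`.
#' @export
simulate_dh_hap_pair <- function(K, h2_D, h2_H, rG, seed = 1L) {
  G0 <- matrix(c(h2_D, rG * sqrt(h2_D * h2_H),
                 rG * sqrt(h2_D * h2_H), h2_H), 2, 2)
  R0 <- diag(c(1 - h2_D, 1 - h2_H))
  set.seed(seed)
  n <- nrow(K)
  u <- sym_sqrt(K) %*% rmat_norm_rows(n, G0)
  Y <- u + rmat_norm_rows(n, R0)
  dimnames(Y) <- list(rownames(K), c("DH", "HAP"))
  list(Y = Y, u = u, G0 = G0, R0 = R0)
}

#' Line-level multi-trait panel with structured genetic correlations
#'
#' Generates a panel of traits whose additive values share a single latent
#' genetic factor: trait j loads sqrt(rho_j) on the factor, so the genetic
#' correlation between traits j and l is sqrt(rho_j * rho_l). Total variance
#' is 1 per trait; heritabilities are set per trait. An optional common
#' residual factor (loading sqrt(rho_e)) emulates shared plot effects.
#'
#' @param K GRM.
#' @param h2 numeric vector of per-trait heritabilities.
#' @param rho numeric vector (same length) of genetic factor loadings
#'   squared; pairwise rG = sqrt(rho_j * rho_l).
#' @param rho_e scalar residual common-factor share (default 0.2).
#' @param seed integer seed.
#' @return list with `Y`, `u`, `G0`, `R0`, and the trait names used.
#' @export
simulate_trait_panel <- function(K, h2, rho, rho_e = 0.2, seed = 1L) {
  stop_if_not(length(h2) == length(rho), "h2 and rho must have equal length")
  t_ <- length(h2)
  lam <- sqrt(rho)
  Cg <- tcrossprod(lam) + diag(1 - rho)        # correlation, unit diagonal
  Dg <- diag(sqrt(h2), t_)
  G0 <- Dg %*% Cg %*% Dg
  Ce <- tcrossprod(rep(sqrt(rho_e), t_)) + diag(1 - rho_e, t_)
  De <- diag(sqrt(1 - h2), t_)
  R0 <- De %*% Ce %*% De
  set.seed(seed)
  n <- nrow(K)
  u <- sym_sqrt(K) %*% rmat_norm_rows(n, G0)
  Y <- u + rmat_norm_rows(n, R0)
  traits <- sprintf("T%02d", seq_len(t_))
  dimnames(Y) <- list(rownames(K), traits)
  dimnames(u) <- dimnames(Y)
  list(Y = Y, u = u, G0 = G0, R0 = R0, traits = traits)
}

#' Trait-assisted CV2 study scenario
#'
#' Builds the synthetic single-environment scenario used to benchmark
#' trait-assisted prediction: `n_secondary` agronomic-like secondary traits
#' (heritability 0.3-0.6) and `n_focal` stalk-like focal traits
#' (heritability 0.15-0.4), genetically correlated through a shared latent
#' factor with pairwise rG in about 0.45-0.8, plus a common plot factor
#' (share `rho_e`) on the residual side. Optionally adds haploid
#' counterpart columns whose additive values correlate `rG_hap` with the
#' corresponding DH trait (equal heritability, independent plot
#' residuals).
#'
#' @param K GRM of the line panel.
#' @param n_secondary,n_focal trait counts (defaults 8 and 18).
#' @param rG_hap DH/haploid genetic correlation for the haploid columns
#'   (default 0.7).
#' @param rho_e shared residual-factor share (default 0.2).
#' @param hap also generate haploid columns (default TRUE).
#' @param seed integer seed.
#' @return list with `Y_dh` (n x (n_secondary + n_focal)), `Y_hap` (or
#'   NULL), true breeding values `u_dh`/`u_hap`, `secondary` and `focal`
#'   trait names, and the generating `h2`/`rho` vectors.
#' @export
simulate_cv2_scenario <- function(K, n_secondary = 8, n_focal = 18,
                                  rG_hap = 0.7, rho_e = 0.2, hap = TRUE,
                                  seed = 1L) {
  set.seed(seed)
  t_ <- n_secondary + n_focal
  h2 <- c(stats::runif(n_secondary, 0.3, 0.6),
          stats::runif(n_focal, 0.15, 0.4))
  rho <- stats::runif(t_, 0.45, 0.8)
  pan <- simulate_trait_panel(K, h2, rho, rho_e = rho_e, seed = seed + 1L)
  secondary <- pan$traits[seq_len(n_secondary)]
  focal <- setdiff(pan$traits, secondary)
  out <- list(Y_dh = pan$Y, u_dh = pan$u, secondary = secondary,
              focal = focal, h2 = h2, rho = rho, G0 = pan$G0)
  if (hap) {
    n <- nrow(K)
    Lk <- sym_sqrt(K)
    # independent genetic deviation with the same covariance structure
    u_ind <- Lk %*% rmat_norm_rows(n, pan$G0)
    u_hap <- rG_hap * pan$u + sqrt(1 - rG_hap^2) * u_ind
    De <- diag(sqrt(1 - h2), t_)
    Ce <- tcrossprod(rep(sqrt(rho_e), t_)) + diag(1 - rho_e, t_)
    R0 <- De %*% Ce %*% De
    Y_hap <- u_hap + rmat_norm_rows(n, R0)
    colnames(Y_hap) <- paste0("HAP_", pan$traits)
    colnames(u_hap) <- colnames(Y_hap)
    rownames(Y_hap) <- rownames(pan$Y)
    out$Y_hap <- Y_hap
    out$u_hap <- u_hap
  }
  out
}

#' Write simulated study files
#'
#' Genotypes as TSV (rows = lines, columns = markers, dosages 0/1/2/NA),
#' the marker map as TSV, and phenotypes as long CSV.
#'
#' @param geno a `genotype_matrix`.
#' @param pheno long phenotype data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_study <- function(geno, pheno, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  gd <- data.frame(line_id = geno$line_ids, geno$dosages, check.names = FALSE)
  utils::write.table(gd, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- file.path(dir, "marker_map.tsv")
  utils::write.table(geno$map, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ppath <- file.path(dir, "phenotypes.csv")
  utils::write.csv(pheno, ppath, row.names = FALSE)
  invisible(c(genotypes = gpath, map = mpath, phenotypes = ppath))
}

#' Read a genotype TSV written by [write_simulated_study()]
#'
#' @param geno_path genotype TSV path.
#' @param map_path marker map TSV path.
#' @param population population label.
#' @return a `genotype_matrix`.
#' @export
read_genotype_tsv <- function(geno_path, map_path, population = "DH") {
  gd <- utils::read.delim(geno_path, check.names = FALSE)
  map <- utils::read.delim(map_path)
  check_map_sorted(map)
  d <- as.matrix(gd[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- gd[[1]]
  stop_if_not(identical(colnames(d), map$marker_id),
              "genotype columns do not match the marker map")
  structure(list(dosages = d, line_ids = gd[[1]],
                 marker_ids = map$marker_id, map = map,
                 population = population),
            class = "genotype_matrix")
}
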