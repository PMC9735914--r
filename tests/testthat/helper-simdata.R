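# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

# Small biparental DH panel (120 lines, 5 chromosomes) and its GRM.
small_panel <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(n_lines = 120, chrom_lengths_cM = rep(150, 5),
                      markers_per_chrom = rep(60, 5), seed = 101)
    sim <- simulate_biparental_dh(cfg)
    qc <- qc_filter(sim$geno)
    K <- compute_grm(qc$geno)
    .fixtures$small <- list(cfg = cfg, sim = sim, geno = qc$geno, K = K)
  }
  .fixtures$small
}

# Full-size panel matching the study scale (187 lines, 10 x 132 markers).
study_panel <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- sim_config(seed = 11)
    sim <- simulate_biparental_dh(cfg)
    qc <- qc_filter(sim$geno)
    .fixtures$study <- list(cfg = cfg, sim = sim, geno = qc$geno,
                            K = compute_grm(qc$geno))
  }
  .fixtures$study
}

# Hand-built genotype_matrix from a dosage matrix (markers on 1 chromosome
# unless a map is supplied).
toy_geno <- function(d, map = NULL) {
  n <- nrow(d); m <- ncol(d)
  line_ids <- rownames(d) %||% sprintf("L%02d", seq_len(n))
  marker_ids <- colnames(d) %||% sprintf("m%02d", seq_len(m))
  if (is.null(map))
    map <- data.frame(marker_id = marker_ids, chromosome = 1L,
                      position_bp = seq_len(m) * 1000L,
                      position_cM = seq_len(m) * 1.0)
  dimnames(d) <- list(line_ids, marker_ids)
  structure(list(dosages = d, line_ids = line_ids, marker_ids = marker_ids,
                 map = map, population = "DH"),
            class = "genotype_matrix")
}

toy_origin <- function(o, map = NULL) {
  n <- nrow(o); m <- ncol(o)
  line_ids <- rownames(o) %||% sprintf("L%02d", seq_len(n))
  marker_ids <- colnames(o) %||% sprintf("m%02d", seq_len(m))
  if (is.null(map))
    map <- data.frame(marker_id = marker_ids, chromosome = 1L,
                      position_bp = seq_len(m) * 1000L,
                      position_cM = seq_len(m) * 1.0)
  dimnames(o) <- list(line_ids, marker_ids)
  structure(list(origins = o, line_ids = line_ids, marker_ids = marker_ids,
                 map = map),
            class = "origin_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
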