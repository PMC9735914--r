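# Marker QC, GRM, parental-origin encoding and recombination counting.

test_that("qc_filter applies strict thresholds per criterion", {
  # marker 1: MAF 0.02 (4 minor alleles in 100 diploid lines) -> removed
  d <- matrix(2L, 100, 3)
  d[1:2, 1] <- 0L                       # 4 copies of the minor allele
  d[1:50, 2] <- 0L                      # MAF 0.5, kept
  d[1:40, 3] <- 0L                      # MAF 0.4, kept
  g <- toy_geno(d)
  out <- qc_filter(g)
  expect_false("m01" %in% out$geno$marker_ids)
  expect_equal(out$report$removed_maf, 1)

  # clean matrix passes untouched
  out2 <- qc_filter(toy_geno(d[, 2:3]))
  expect_equal(dim(out2$geno$dosages), dim(d[, 2:3]))
  expect_match(out2$report$convention, "boundary values fail")

  # line with 25% missing removed (threshold < 20%)
  d3 <- matrix(rep(c(rep(0L, 5), rep(2L, 5)), 8), 10, 8)
  d3[1, 1:2] <- NA                      # 2/8 = 25% missing
  out3 <- qc_filter(toy_geno(d3))
  expect_false("L01" %in% out3$geno$line_ids)
  expect_equal(out3$report$removed_line_missing, 1)

  # boundary missing rate exactly at the threshold fails (strict <)
  d4 <- matrix(rep(c(rep(0L, 4), rep(2L, 4)), 2), 8, 2)
  d4[1:2, 1] <- NA                      # missing rate exactly 0.25
  out4 <- qc_filter(toy_geno(d4), marker_miss_max = 0.25)
  expect_false("m01" %in% out4$geno$marker_ids)

  expect_error(qc_filter(toy_geno(matrix(2L, 5, 2))), "no data")
})

test_that("qc_filter is idempotent on clean data", {
  p <- small_panel()
  once <- qc_filter(p$sim$geno)
  twice <- qc_filter(once$geno)
  expect_equal(twice$geno$dosages, once$geno$dosages)
  expect_equal(twice$report$n_markers_in, twice$report$n_markers_out)
})

test_that("compute_grm matches the VanRaden formula element by element", {
  d <- matrix(c(0L, 2L, 2L, 0L,
                2L, 2L, 0L, NA,
                0L, 0L, 2L, 2L), 4, 3)
  g <- toy_geno(d)
  K <- compute_grm(g)

  # independent scalar-loop oracle
  dd <- d
  storage.mode(dd) <- "double"
  dd[is.na(d)] <- colMeans(d, na.rm = TRUE)[col(d)[is.na(d)]]
  p <- colMeans(dd) / 2
  denom <- 2 * sum(p * (1 - p))
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    s <- 0
    for (m in 1:3) s <- s + (dd[i, m] - 2 * p[m]) * (dd[j, m] - 2 * p[m])
    ref[i, j] <- s / denom
  }
  expect_equal(unname(K$matrix), ref, tolerance = 1e-12)

  # identical homozygous lines: off-diagonal equals diagonal
  d2 <- rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 0L, 2L), c(2L, 0L, 2L, 0L))
  K2 <- compute_grm(toy_geno(d2))
  expect_equal(K2$matrix[1, 2], K2$matrix[1, 1])

  # PSD up to tolerance
  p3 <- small_panel()
  ev <- eigen(compute_grm(p3$geno)$matrix, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)

  expect_error(compute_grm(toy_geno(matrix(2L, 4, 3))), "monomorphic")
})

test_that("GRM of a DH panel shows inbreeding and full-sib relatedness", {
  p <- small_panel()
  K <- compute_grm(p$geno)$matrix
  expect_equal(mean(diag(K)), 2, tolerance = 0.15)
  off <- K[upper.tri(K)]
  expect_gt(mean(off > 0.5), 0.1)   # many elevated full-sib pairs
})

test_that("parental origin encoding follows the identity rules", {
  p1 <- c(2L, 2L, 2L, 2L)
  p2 <- c(0L, 0L, 0L, 0L)
  d <- rbind(c(2L, 2L, 2L, 2L),      # identical to P1
             c(2L, 0L, 1L, NA),     # mixed with het and missing
             c(0L, 0L, 0L, 0L))     # identical to P2
  o <- encode_parental_origin(toy_geno(d), p1, p2)
  expect_true(all(o$origins[1, ] == "P1"))
  expect_true(all(o$origins[3, ] == "P2"))
  expect_equal(unname(o$origins[2, ]), c("P1", "P2", NA, NA))

  # uninformative markers (parents agree) are dropped
  o2 <- encode_parental_origin(toy_geno(d), c(2L, 2L, 2L, 2L),
                               c(0L, 0L, 2L, 0L))
  expect_equal(length(o2$marker_ids), 3L)

  expect_error(encode_parental_origin(toy_geno(d), p1[1:3], p2),
               "not aligned")
})

test_that("recombination counting skips missing markers", {
  o <- toy_origin(rbind(c("P1", "P1", "P1", "P1", "P1", "P1"),
                        c("P1", "P2", "P1", "P2", "P1", "P2"),
                        c("P1", NA, "P2", "P2", NA, "P1")))
  expect_warning(res <- count_recombinations(
    toy_origin(rbind(c(NA, NA, NA, NA, NA, "P1")))), "informative")
  expect_equal(res$n_recombinations, 0L)

  counts <- count_recombinations(o)
  expect_equal(counts$n_recombinations, c(0L, 5L, 2L))
})

test_that("recombination counts recover the gamete's true switch points", {
  cfg <- sim_config(n_lines = 40, chrom_lengths_cM = rep(150, 2),
                    markers_per_chrom = rep(80, 2), selfing_fraction = 0,
                    seed = 23)
  sim <- simulate_biparental_dh(cfg)
  counted <- count_recombinations(sim$origins)

  # independent oracle: run-length encode each line's origin mosaic
  for (i in c(1, 10, 25)) {
    for (chr in 1:2) {
      cols <- sim$origins$map$chromosome == chr
      x <- sim$origins$origins[i, cols]
      truth <- length(rle(x)$values) - 1L
      got <- counted$n_recombinations[counted$line_id ==
                                        sim$origins$line_ids[i] &
                                        counted$chromosome == chr]
      expect_equal(got, truth)
    }
  }
})

test_that("graphical genotype export merges same-origin runs", {
  o <- toy_origin(rbind(rep("P1", 4),
                        c("P1", "P2", "P1", "P2")))
  segs <- export_graphical_genotypes(o)
  s1 <- segs[segs$line_id == "L01", ]
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$start_bp, 1000L)
  expect_equal(s1$end_bp, 4000L)
  s2 <- segs[segs$line_id == "L02", ]
  expect_equal(nrow(s2), 4L)

  # hand merge of a 2-line toy incl. missing-absorbed run
  o2 <- toy_origin(rbind(c("P1", "P1", NA, "P2", "P2"),
                         c("P2", "P2", "P2", "P2", "P2")))
  segs2 <- export_graphical_genotypes(o2)
  l1 <- segs2[segs2$line_id == "L01", ]
  expect_equal(l1$origin, c("P1", "P2"))
  expect_equal(l1$start_bp, c(1000L, 4000L))
  expect_equal(l1$end_bp, c(2000L, 5000L))

  path <- tempfile(fileext = ".tsv")
  export_graphical_genotypes(o2, path)
  expect_true(file.exists(path))
  unlink(path)
})
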