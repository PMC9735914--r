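# Marker QC, genomic relationship matrices, parental-origin encoding and
# recombination counting.

#' SNP and line quality control
#'
#' Applies the chip-filtering criteria in two stages: markers first
#' ((i) MAF, (ii) marker missing rate, (iii) marker heterozygosity rate),
#' then lines ((iv) line missing rate, (v) line heterozygosity rate), in a
#' single pass. All thresholds are strict inequalities: a marker is kept
#' when MAF > `maf_min` and rates are < their maxima, so boundary values
#' fail (this convention is recorded in the report header).
#'
#' @param g a `genotype_matrix` with dosages in \{0, 1, 2, NA\}.
#' @param maf_min minimum minor allele frequency (exclusive), default 0.05.
#' @param marker_miss_max maximum marker missing rate (exclusive), 0.20.
#' @param marker_het_max maximum marker heterozygosity rate (exclusive), 0.10.
#' @param line_miss_max maximum line missing rate (exclusive), 0.20.
#' @param line_het_max maximum line heterozygosity rate (exclusive), 0.20.
#' @return list with `geno` (filtered `genotype_matrix`) and `report`
#'   (counts removed per criterion plus the threshold convention).
#' @export
qc_filter <- function(g, maf_min = 0.05, marker_miss_max = 0.20,
                      marker_het_max = 0.10, line_miss_max = 0.20,
                      line_het_max = 0.20) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  stop_if_not(all(d %in% c(0L, 1L, 2L, NA)), "dosages must be 0/1/2/NA")

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss_m <- colMeans(is.na(d))
  het_m <- colMeans(d == 1L, na.rm = TRUE)
  het_m[is.nan(het_m)] <- 0
  maf[is.nan(maf)] <- 0
  fail_maf <- !(maf > maf_min)
  fail_miss_m <- !(miss_m < marker_miss_max)
  fail_het_m <- !(het_m < marker_het_max)
  keep_m <- !(fail_maf | fail_miss_m | fail_het_m)

  d2 <- d[, keep_m, drop = FALSE]
  miss_l <- rowMeans(is.na(d2))
  het_l <- rowMeans(d2 == 1L, na.rm = TRUE)
  het_l[is.nan(het_l)] <- 0
  fail_miss_l <- !(miss_l < line_miss_max)
  fail_het_l <- !(het_l < line_het_max)
  keep_l <- !(fail_miss_l | fail_het_l)

  if (!any(keep_m) || !any(keep_l))
    stop("no data left after QC filtering", call. = FALSE)

  out <- g
  out$dosages <- d2[keep_l, , drop = FALSE]
  out$line_ids <- g$line_ids[keep_l]
  out$marker_ids <- g$marker_ids[keep_m]
  out$map <- g$map[keep_m, , drop = FALSE]
  report <- list(
    convention = "strict thresholds: boundary values fail (MAF must exceed maf_min; rates must be below their maxima)",
    order = "markers (i)-(iii) first, then lines (iv)-(v), single pass",
    n_markers_in = ncol(d), n_lines_in = nrow(d),
    removed_maf = sum(fail_maf),
    removed_marker_missing = sum(fail_miss_m & !fail_maf),
    removed_marker_het = sum(fail_het_m & !fail_maf & !fail_miss_m),
    removed_line_missing = sum(fail_miss_l),
    removed_line_het = sum(fail_het_l & !fail_miss_l),
    n_markers_out = sum(keep_m), n_lines_out = sum(keep_l))
  list(geno = out, report = report)
}

#' VanRaden (method 1) genomic relationship matrix
#'
#' Missing dosages are imputed to the per-marker mean; dosages are centered
#' by twice the allele frequency and the cross-product is divided by
#' `2 * sum(p * (1 - p))`.
#'
#' @param g a `genotype_matrix` (post-QC).
#' @return a `grm` object: list with `matrix` (n x n, symmetric PSD up to
#'   numerical tolerance) and `line_ids`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; GRM denominator is zero", call. = FALSE)
  W <- sweep(d, 2, 2 * p)
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(g$line_ids, g$line_ids)
  structure(list(matrix = K, line_ids = g$line_ids), class = "grm")
}

#' Encode parental origin of marker genotypes
#'
#' For markers where the two parents are homozygous and different
#' (informative markers), each line's call is coded "P1" if identical to
#' parent 1, "P2" if identical to parent 2, and NA when heterozygous or
#' missing (heterozygous calls in a DH panel are likely genotyping errors).
#' Markers where the parents agree are dropped as uninformative.
#'
#' @param g a `genotype_matrix`.
#' @param p1,p2 parental dosage vectors aligned to `g`'s markers.
#' @return an `origin_matrix`: `origins` (n x m_informative, "P1"/"P2"/NA),
#'   `line_ids`, `marker_ids`, `map`.
#' @export
encode_parental_origin <- function(g, p1, p2) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- ncol(g$dosages)
  stop_if_not(length(p1) == m && length(p2) == m,
              "parent rows are not aligned with the genotype matrix")
  informative <- !is.na(p1) & !is.na(p2) & p1 != p2 &
    p1 %in% c(0L, 2L) & p2 %in% c(0L, 2L)
  d <- g$dosages[, informative, drop = FALSE]
  p1i <- p1[informative]
  p2i <- p2[informative]
  o <- matrix(NA_character_, nrow(d), ncol(d), dimnames = dimnames(d))
  o[sweep(d, 2, p1i, `==`)] <- "P1"
  o[sweep(d, 2, p2i, `==`)] <- "P2"
  o[d == 1L] <- NA_character_
  structure(list(origins = o, line_ids = g$line_ids,
                 marker_ids = g$marker_ids[informative],
                 map = g$map[informative, , drop = FALSE]),
            class = "origin_matrix")
}

#' Count recombination events per line and chromosome
#'
#' A recombination is a switch of parental origin between consecutive
#' non-missing informative markers along a chromosome; missing markers are
#' skipped, never counted as switches.
#'
#' @param o an `origin_matrix` (markers sorted by position within
#'   chromosome).
#' @return data.frame `line_id` x `chromosome` -> `n_recombinations`.
#' @export
count_recombinations <- function(o) {
  stopifnot(inherits(o, "origin_matrix"))
  check_map_sorted(o$map)
  chroms <- unique(o$map$chromosome)
  res <- expand.grid(line_id = o$line_ids, chromosome = chroms,
                     stringsAsFactors = FALSE)
  res$n_recombinations <- 0L
  warned <- FALSE
  for (chr in chroms) {
    cols <- which(o$map$chromosome == chr)
    sub <- o$origins[, cols, drop = FALSE]
    counts <- apply(sub, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) return(NA_integer_)
      sum(x[-1] != x[-length(x)])
    })
    low_info <- is.na(counts)
    if (any(low_info) && !warned) {
      warning("some line/chromosome combinations have < 2 informative markers; their count is reported as 0",
              call. = FALSE)
      warned <- TRUE
    }
    counts[low_info] <- 0L
    res$n_recombinations[res$chromosome == chr] <- counts
  }
  res
}

#' Export graphical genotypes as a segment table
#'
#' Merges runs of identical parental origin into segments (1-based,
#' closed `[start_bp, end_bp]` intervals spanning the first to last marker
#' of each run; missing markers are absorbed into the surrounding runs by
#' skipping). Lines are sorted by genotypic similarity to parent 1.
#'
#' @param o an `origin_matrix`.
#' @param path optional TSV output path; when `NULL` the table is only
#'   returned.
#' @return data.frame with `line_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `origin`, invisibly written to `path` when given.
#' @export
export_graphical_genotypes <- function(o, path = NULL) {
  stopifnot(inherits(o, "origin_matrix"))
  check_map_sorted(o$map)
  p1_frac <- rowMeans(o$origins == "P1", na.rm = TRUE)
  ord <- order(p1_frac, decreasing = TRUE)
  segs <- list()
  for (chr in unique(o$map$chromosome)) {
    cols <- which(o$map$chromosome == chr)
    pos <- o$map$position_bp[cols]
    for (i in ord) {
      x <- o$origins[i, cols]
      keep <- !is.na(x)
      if (!any(keep)) next
      xx <- x[keep]
      pp <- pos[keep]
      r <- rle(xx)
      ends <- cumsum(r$lengths)
      starts <- c(1, head(ends, -1) + 1)
      segs[[length(segs) + 1]] <- data.frame(
        line_id = o$line_ids[i], chromosome = chr,
        start_bp = pp[starts], end_bp = pp[ends], origin = r$values)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  if (!is.null(path)) {
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop("failed to write segment table: ",
                                conditionMessage(e), call. = FALSE))
  }
  out
}

#' Plot graphical genotypes
#'
#' Thin ggplot2 layer over [export_graphical_genotypes()]: one horizontal
#' bar per line and chromosome, colored by parental origin.
#'
#' @param o an `origin_matrix`.
#' @return a ggplot object.
#' @export
plot_graphical_genotypes <- function(o) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  segs <- export_graphical_genotypes(o)
  segs$line_id <- factor(segs$line_id, levels = unique(segs$line_id))
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_bp, xmax = .data$end_bp,
      ymin = as.integer(.data$line_id) - 0.45,
      ymax = as.integer(.data$line_id) + 0.45,
      fill = .data$origin)) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(P1 = "#3B6FB6", P2 = "#C0392B")) +
    ggplot2::labs(x = "physical position (bp)", y = "line")
}

#' Write a GRM as TSV with a line-id header
#' @param K a `grm`.
#' @param path output path.
#' @export
write_grm_tsv <- function(K, path) {
  stopifnot(inherits(K, "grm"))
  df <- data.frame(line_id = K$line_ids, K$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GRM written by [write_grm_tsv()]
#' @param path TSV path.
#' @return a `grm`.
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  structure(list(matrix = M, line_ids = df[[1]]), class = "grm")
}
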