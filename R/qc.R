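#' Cell quality control
#'
#' Removes poor-quality cells by two criteria: total reads mapping to exons
#' below `exon_min`, and mitochondrial read fraction above `mito_max`.
#' Optionally, cells in which an unusually large share of genes look
#' abnormally amplified are flagged: a gene counts as amplified in a cell when
#' its normalized (library-size-scaled) count exceeds the across-cell median
#' by more than `amplification_z` MADs, and a cell fails when the amplified
#' fraction exceeds `amplification_frac`. The amplification flag is off by
#' default (`amplification_z = NULL`).
#'
#' @param counts a [count_matrix()].
#' @param qc_table optional tibble with columns `cell_id`, `exon_reads`,
#'   `mito_fraction`. When absent, `exon_reads` falls back to the column sums
#'   of `counts` and `mito_fraction` to 0.
#' @param exon_min minimum exon read count per cell (default 5e5).
#' @param mito_max maximum mitochondrial fraction (default 0.10).
#' @param amplification_z MAD multiplier for the amplification flag, or
#'   `NULL` to disable.
#' @param amplification_frac fraction of amplified genes above which a cell is
#'   flagged (default 0.05).
#' @return A list with `report` (one row per input cell: `cell_id`,
#'   `exon_reads`, `mito_fraction`, `amplification_flag`, `pass`) and
#'   `counts` (the filtered [count_matrix()]).
#' @export
qc_cells <- function(counts, qc_table = NULL, exon_min = 5e5, mito_max = 0.10,
                     amplification_z = NULL, amplification_frac = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(qc_table)) {
    qc_table <- tibble(
      cell_id = counts$cells,
      exon_reads = rowSums(counts$counts),
      mito_fraction = 0
    )
  }
  if (!all(counts$cells %in% qc_table$cell_id)) {
    abort("qc_table does not cover all cells in the count matrix")
  }
  qc_table <- qc_table[match(counts$cells, qc_table$cell_id), ]
  amp <- rep(FALSE, length(counts$cells))
  if (!is.null(amplification_z)) {
    # scale by library size so depth differences do not masquerade as amplification
    lib <- rowSums(counts$counts)
    lib <- lib / mean(lib)
    lib[lib == 0] <- 1
    norm <- counts$counts / lib
    med <- apply(norm, 2, median)
    madv <- apply(norm, 2, mad)
    madv[madv == 0] <- Inf
    high <- sweep(sweep(norm, 2, med, "-"), 2, madv, "/") > amplification_z
    amp <- rowMeans(high) > amplification_frac
  }
  report <- tibble(
    cell_id = qc_table$cell_id,
    exon_reads = qc_table$exon_reads,
    mito_fraction = qc_table$mito_fraction,
    amplification_flag = amp,
    pass = qc_table$exon_reads >= exon_min &
      qc_table$mito_fraction <= mito_max & !amp
  )
  keep <- report$cell_id[report$pass]
  if (length(keep) == 0) abort("no cells survive quality control")
  list(report = report, counts = subset_count_matrix(counts, cells = keep))
}

#' Median-of-ratios size factors
#'
#' Per-cell scaling factors: each cell's factor is the median, over reference
#' genes, of the ratio of the cell's count to the gene's geometric mean across
#' cells. Only genes with non-zero counts in every cell contribute (the
#' geometric-mean reference is undefined otherwise). Estimation is delegated
#' to the standard median-of-ratios implementation in DESeq2.
#'
#' @param counts a [count_matrix()].
#' @return The [count_matrix()] with `size_factors` and `normalized` filled
#'   in (`normalized = counts / size_factor`, per cell).
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  all_nonzero <- colSums(counts$counts > 0) == nrow(counts$counts)
  if (!any(all_nonzero)) {
    abort(paste0(
      "no gene has non-zero counts in every cell; the median-of-ratios ",
      "reference is undefined. Consider a pseudo-reference (e.g. shifted-log) ",
      "normalization for very sparse matrices."
    ))
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(t(counts$counts))
  counts$size_factors <- setNames(as.numeric(sf), counts$cells)
  counts$normalized <- counts$counts / counts$size_factors
  counts
}

#' Filter lowly expressed genes
#'
#' A gene is kept when its average normalized count across cells is at least
#' `min_mean` (default 10); lowly expressed genes mostly reflect technical
#' variability and are removed before any noise or kinetics computation.
#'
#' @param counts a normalized [count_matrix()] (run [size_factors()] first).
#' @param min_mean minimum mean normalized count.
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(counts, min_mean = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(counts$normalized)) {
    abort("normalize first: run size_factors() before filter_expressed()")
  }
  keep <- counts$genes[colMeans(counts$normalized) >= min_mean]
  subset_count_matrix(counts, genes = keep)
}
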