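#' Cell-by-gene count matrix container
#'
#' A light container for single-cell RNA-seq counts: an integer matrix with
#' cells as rows and genes as columns, plus (once computed) the per-cell size
#' factors and the normalized matrix. All per-gene statistics in the package
#' consume either this container or the tidy tibbles derived from it.
#'
#' @param counts numeric matrix, cells x genes, non-negative integers.
#' @param cells,genes character vectors of unique identifiers; default to the
#'   dimnames of `counts`.
#' @param normalized optional matrix of the same shape: counts divided by the
#'   per-cell size factor.
#' @param size_factors optional named numeric vector of positive per-cell
#'   factors.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cells = rownames(counts),
                         genes = colnames(counts),
                         normalized = NULL, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(cells) || is.null(genes)) {
    abort("`counts` must have cell and gene identifiers (dimnames or explicit).")
  }
  cells <- as.character(cells)
  genes <- as.character(genes)
  if (length(cells) != nrow(counts) || length(genes) != ncol(counts)) {
    abort("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(cells)) abort("duplicate cell identifiers")
  if (anyDuplicated(genes)) abort("duplicate gene identifiers")
  if (anyNA(counts)) abort("counts contain missing values")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts != trunc(counts))) abort("counts must be integral")
  if (length(counts) == 0 || max(counts) <= .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  dimnames(counts) <- list(cells, genes)
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!identical(dim(normalized), dim(counts))) {
      abort("`normalized` must have the same shape as `counts`")
    }
    if (any(normalized < 0)) abort("`normalized` must be non-negative")
    dimnames(normalized) <- dimnames(counts)
  }
  if (!is.null(size_factors)) {
    if (any(size_factors <= 0)) abort("size factors must be positive")
    size_factors <- setNames(as.numeric(size_factors), cells)
  }
  structure(
    list(counts = counts, cells = cells, genes = genes,
         normalized = normalized, size_factors = size_factors),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes%s\n",
              length(x$cells), length(x$genes),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#'
#' @param x a [count_matrix()].
#' @param ... unused.
#' @return A tibble with columns `cell`, `gene`, `count` and, when available,
#'   `normalized`.
#' @exportS3Method tibble::as_tibble
as_tibble.count_matrix <- function(x, ...) {
  out <- tibble(
    cell = rep(x$cells, times = length(x$genes)),
    gene = rep(x$genes, each = length(x$cells)),
    count = as.vector(x$counts)
  )
  if (!is.null(x$normalized)) out$normalized <- as.vector(x$normalized)
  out
}

#' Read a cell-by-gene count matrix
#'
#' Supports a plain TSV (with a leading id column) and MatrixMarket triplet
#' format with two sidecar id files. Counts are validated: negative or
#' non-integer entries are rejected.
#'
#' @param path file path. For `format = "mtx"` the cell and gene ids are read
#'   from `cells_file` / `genes_file` (one id per line; rows of the matrix are
#'   genes, columns are cells, the common single-cell convention).
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_as for TSV: `"columns"` (rows are cells, the default) or
#'   `"rows"`.
#' @param cells_file,genes_file sidecar id files for `format = "mtx"`;
#'   default `<path>.cells` and `<path>.genes`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              genes_as = c("columns", "rows"),
                              cells_file = paste0(path, ".cells"),
                              genes_file = paste0(path, ".genes")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) abort(paste0("non-numeric count entries in ", path))
    if (genes_as == "columns") {
      rownames(m) <- ids
      cm <- count_matrix(m)
    } else {
      rownames(m) <- ids
      cm <- count_matrix(t(m))
    }
  } else {
    if (!file.exists(cells_file) || !file.exists(genes_file)) {
      abort("mtx format needs both sidecar id files (cells_file, genes_file)")
    }
    m <- as.matrix(Matrix::readMM(path))
    cells <- readr::read_lines(cells_file)
    genes <- readr::read_lines(genes_file)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort("mtx dimensions do not match sidecar id files (rows = genes, cols = cells)")
    }
    dimnames(m) <- list(genes, cells)
    cm <- count_matrix(t(m))
  }
  cm
}

#' Write a count matrix
#'
#' Inverse of [read_count_matrix()]; round-trips are lossless.
#'
#' @inheritParams read_count_matrix
#' @param x a [count_matrix()].
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx"),
                               genes_as = c("columns", "rows"),
                               cells_file = paste0(path, ".cells"),
                               genes_file = paste0(path, ".genes")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (format == "tsv") {
    if (genes_as == "columns") {
      df <- as.data.frame(x$counts)
      df <- cbind(cell = x$cells, df)
    } else {
      df <- as.data.frame(t(x$counts))
      df <- cbind(gene = x$genes, df)
    }
    readr::write_tsv(as_tibble(df), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(x$counts), sparse = TRUE), path)
    readr::write_lines(x$cells, cells_file)
    readr::write_lines(x$genes, genes_file)
  }
  invisible(path)
}

# subset a count_matrix by cell and/or gene ids, keeping derived slots in step
subset_count_matrix <- function(x, cells = x$cells, genes = x$genes) {
  cm <- count_matrix(
    x$counts[cells, genes, drop = FALSE],
    normalized = if (!is.null(x$normalized)) x$normalized[cells, genes, drop = FALSE],
    size_factors = if (!is.null(x$size_factors)) x$size_factors[cells]
  )
  cm
}
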