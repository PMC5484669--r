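#' Read gene annotation (TSS, strand, length)
#'
#' Internal coordinates are 1-based inclusive. BED input (0-based, half-open)
#' is converted at the boundary: internal start = BED start + 1, internal
#' end = BED end. The TSS is the 5' end of the interval: internal start on the
#' `+` strand, internal end on the `-` strand. Gene length defaults to the
#' annotated span (end - start + 1 on internal coordinates); supply your own
#' length column downstream if a different definition is wanted.
#'
#' @param path a BED6 file (chrom, start, end, name, score, strand) or a GTF
#'   subset containing gene records with a `gene_id` attribute.
#' @param dialect `"bed6"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `tss`, `strand`, `length`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed6", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "bed6") {
    df <- readr::read_tsv(
      path,
      col_names = c("chromosome", "start0", "end0", "gene_id", "score", "strand"),
      col_types = "ciicdc", comment = "#"
    )
    ann <- tibble(
      gene_id = df$gene_id,
      chromosome = df$chromosome,
      start = df$start0 + 1L,
      end = df$end0,
      strand = df$strand
    )
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("the gtf dialect needs the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    d <- as.data.frame(gr[gr$type == "gene"])
    ann <- tibble(
      gene_id = as.character(d$gene_id),
      chromosome = as.character(d$seqnames),
      start = d$start,
      end = d$end,
      strand = as.character(d$strand)
    )
  }
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  bad_strand <- !ann$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("unknown strand symbol(s): ",
                 paste(unique(ann$strand[bad_strand]), collapse = ", ")))
  }
  if (any(ann$start > ann$end)) {
    abort("invalid interval(s): start > end after coordinate conversion")
  }
  if (any(ann$start < 1)) abort("coordinates must be positive (1-based)")
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene_id in annotation")
  ann <- ann |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      length = .data$end - .data$start + 1L
    ) |>
    select("gene_id", "chromosome", "start", "end", "tss", "strand", "length")
  as_tibble(ann)
}

#' Write gene annotation as BED6
#'
#' Inverse of [read_gene_annotation()] for the bed6 dialect (coordinates are
#' converted back to 0-based half-open).
#'
#' @param ann annotation tibble as returned by [read_gene_annotation()].
#' @param path output file.
#' @export
write_gene_annotation <- function(ann, path) {
  out <- tibble(
    chromosome = ann$chromosome,
    start0 = ann$start - 1L,
    end0 = ann$end,
    gene_id = ann$gene_id,
    score = 0,
    strand = ann$strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a per-gene chromatin-state table
#'
#' A two-column TSV mapping gene id to one of the four promoter states:
#' `Active` (active RNAPII, no Polycomb marks), `PRCa` (Polycomb marks plus
#' active RNAPII), `PRCr` (Polycomb marks with unproductive RNAPII) or
#' `other`.
#'
#' @param path TSV with columns `gene_id`, `state` (header optional in that
#'   order).
#' @return A tibble with columns `gene_id`, `state`.
#' @export
read_chromatin_states <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "state") %in% names(df))) {
    names(df)[1:2] <- c("gene_id", "state")
  }
  df <- as_tibble(df[, c("gene_id", "state")])
  bad <- !df$state %in% c("Active", "PRCa", "PRCr", "other")
  if (any(bad)) {
    abort(paste0("unknown chromatin state(s): ",
                 paste(unique(df$state[bad]), collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) abort("gene classified more than once")
  df
}

#' Read a per-gene mRNA decay-rate table
#'
#' @param path TSV with columns `gene_id`, `decay` (rate per unit time, > 0).
#' @return A tibble with columns `gene_id`, `decay`.
#' @export
read_decay_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "decay") %in% names(df))) {
    names(df)[1:2] <- c("gene_id", "decay")
  }
  df <- as_tibble(df[, c("gene_id", "decay")])
  if (any(!is.finite(df$decay)) || any(df$decay <= 0)) {
    abort("decay rates must be finite and positive")
  }
  df
}

#' Read a promoter/enhancer interaction list
#'
#' A BEDPE-like TSV: the first six columns are the two anchors (0-based
#' half-open, converted to internal 1-based coordinates), followed by
#' `a_kind`, `b_kind` in `{promoter, enhancer}` and `enhancer_class` in
#' `{active, intermediate, poised}` (required whenever either anchor is an
#' enhancer, empty otherwise). Promoter anchors are mapped to gene ids by TSS
#' overlap: a gene is assigned when its TSS falls within the anchor extended
#' by `promoter_window` bp on each side. Promoter anchors overlapping no TSS
#' are retained with an empty gene list and a warning.
#'
#' @param path input TSV (header optional; columns in the order above).
#' @param annotation annotation tibble from [read_gene_annotation()]; if
#'   `NULL`, gene lists are left empty.
#' @param promoter_window half-width in bp for TSS-to-anchor assignment
#'   (default 2000, i.e. a 2 kb window around the TSS).
#' @return A tibble of class `interaction_set` with anchor coordinates,
#'   kinds, `enhancer_class` and list-columns `genes_a`, `genes_b`.
#' @export
read_interactions <- function(path, annotation = NULL, promoter_window = 2000) {
  cn <- c("chr_a", "start_a", "end_a", "chr_b", "start_b", "end_b",
          "a_kind", "b_kind", "enhancer_class")
  first <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  has_header <- identical(first[1], "chr_a")
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE,
                        na = c("", "NA", "."))
  names(df)[seq_along(cn)] <- cn
  df <- as_tibble(df[, cn])
  df$start_a <- df$start_a + 1L
  df$start_b <- df$start_b + 1L
  if (any(df$start_a > df$end_a) || any(df$start_b > df$end_b)) {
    abort("invalid anchor interval(s): start >= end in BEDPE input")
  }
  bad_kind <- !df$a_kind %in% c("promoter", "enhancer") |
    !df$b_kind %in% c("promoter", "enhancer")
  if (any(bad_kind)) abort("anchor kinds must be 'promoter' or 'enhancer'")
  is_enh <- df$a_kind == "enhancer" | df$b_kind == "enhancer"
  if (any(is_enh & is.na(df$enhancer_class))) {
    abort("enhancer interaction(s) lacking an enhancer_class")
  }
  if (any(!is_enh & !is.na(df$enhancer_class))) {
    abort("enhancer_class given for promoter-promoter interaction(s)")
  }
  bad_class <- !is.na(df$enhancer_class) &
    !df$enhancer_class %in% c("active", "intermediate", "poised")
  if (any(bad_class)) {
    abort("enhancer_class must be active, intermediate or poised")
  }
  df$genes_a <- map_anchor_genes(df$chr_a, df$start_a, df$end_a, df$a_kind,
                                 annotation, promoter_window)
  df$genes_b <- map_anchor_genes(df$chr_b, df$start_b, df$end_b, df$b_kind,
                                 annotation, promoter_window)
  if (!is.null(annotation)) {
    n_unmapped <- sum((df$a_kind == "promoter" & lengths(df$genes_a) == 0) |
                        (df$b_kind == "promoter" & lengths(df$genes_b) == 0))
    if (n_unmapped > 0) {
      warn(sprintf("%d promoter anchor(s) overlap no annotated TSS; retained with empty gene list",
                   n_unmapped))
    }
  }
  class(df) <- c("interaction_set", class(df))
  df
}

# assign genes whose TSS +- window overlaps each promoter anchor
map_anchor_genes <- function(chr, start, end, kind, annotation, window) {
  if (is.null(annotation)) return(rep(list(character(0)), length(chr)))
  by_chr <- split(annotation[, c("gene_id", "tss")], annotation$chromosome)
  pmap(list(chr, start, end, kind), function(ch, s, e, k) {
    if (k != "promoter") return(character(0))
    g <- by_chr[[ch]]
    if (is.null(g)) return(character(0))
    g$gene_id[g$tss >= s - window & g$tss <= e + window]
  })
}

#' Write an interaction list
#'
#' Inverse of [read_interactions()] (gene lists are recomputed on read, not
#' serialized; anchors go back to 0-based half-open coordinates).
#'
#' @param x an `interaction_set` tibble.
#' @param path output file.
#' @export
write_interactions <- function(x, path) {
  out <- tibble(
    chr_a = x$chr_a, start_a = x$start_a - 1L, end_a = x$end_a,
    chr_b = x$chr_b, start_b = x$start_b - 1L, end_b = x$end_b,
    a_kind = x$a_kind, b_kind = x$b_kind, enhancer_class = x$enhancer_class
  )
  readr::write_tsv(out, path, col_names = TRUE)
  invisible(path)
}
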