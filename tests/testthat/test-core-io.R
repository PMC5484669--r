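test_that("count matrix TSV round-trip is lossless and validated", {
  m <- matrix(c(0L, 5L, 2L, 0L, 1L, 1L), nrow = 3, byrow = TRUE)
  cm <- toy_counts(m, cells = c("a", "b", "c"), genes = c("gA", "gB"))
  expect_equal(unname(cm$counts), matrix(c(0L, 5L, 2L, 0L, 1L, 1L), 3,
                                         byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$cells, cm$cells)

  # genes-as-rows orientation round-trips too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, path2, genes_as = "rows")
  back2 <- read_count_matrix(path2, genes_as = "rows")
  expect_identical(back2$counts, cm$counts)
})

test_that("MatrixMarket triplet round-trip preserves counts; non-integer entries rejected", {
  m <- matrix(rpois(12, 3), 3, 4)
  cm <- toy_counts(m)
  path <- withr::local_tempfile(fileext = ".mtx")
  write_count_matrix(cm, path, format = "mtx")
  back <- read_count_matrix(path, format = "mtx")
  expect_identical(unname(back$counts), unname(cm$counts))
  expect_identical(back$genes, cm$genes)

  # plant a fractional entry in the triplet body
  lines <- readLines(path)
  body <- which(!startsWith(lines, "%"))[-1]
  parts <- strsplit(lines[body[1]], " ")[[1]]
  parts[3] <- "2.5"
  lines[body[1]] <- paste(parts, collapse = " ")
  writeLines(lines, path)
  expect_error(read_count_matrix(path, format = "mtx"), "integral")
})

test_that("count matrix contract rejects negatives, non-integers and duplicate ids", {
  expect_error(count_matrix(matrix(-1, 1, 1, dimnames = list("c", "g"))),
               "non-negative")
  expect_error(count_matrix(matrix(1.5, 1, 1, dimnames = list("c", "g"))),
               "integral")
  m <- matrix(0L, 2, 2, dimnames = list(c("c", "c"), c("g1", "g2")))
  expect_error(count_matrix(m), "duplicate cell")
})

test_that("BED6 import converts 0-based half-open to 1-based TSS, strand-aware", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tgeneA\t0\t+",
               "chr1\t99\t200\tgeneB\t0\t-"), path)
  ann <- read_gene_annotation(path)
  expect_equal(ann$tss[ann$gene_id == "geneA"], 100)
  expect_equal(ann$tss[ann$gene_id == "geneB"], 200)
  expect_equal(ann$length, c(101, 101))

  # round trip back through the writer
  out <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(ann, out)
  expect_equal(read_gene_annotation(out), ann)
})

test_that("GTF gene records import with 1-based coordinates kept as-is", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "gene", "100", "200", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr2", "src", "gene", "500", "900", ".", "-", ".",
          'gene_id "gB";', sep = "\t")
  ), path)
  ann <- read_gene_annotation(path, dialect = "gtf")
  expect_equal(ann$tss[ann$gene_id == "gA"], 100)
  expect_equal(ann$tss[ann$gene_id == "gB"], 900)
  expect_equal(ann$length, c(101, 401))
})

test_that("annotation contract: bad strand and inverted intervals error", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneA\t0\t*", path)
  expect_error(read_gene_annotation(path), "strand")
  writeLines("chr1\t300\t200\tgeneA\t0\t+", path)
  expect_error(read_gene_annotation(path), "start")
})

test_that("interaction reader maps promoter anchors to genes and enforces enhancer class", {
  ann <- toy_annotation(3, spacing = 1e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    # promoter-promoter at 1 Mb and 2 Mb (0-based anchors around the TSSs)
    "chr1\t999000\t1001000\tchr1\t1999000\t2001000\tpromoter\tpromoter\t",
    # promoter-enhancer with class
    "chr1\t999000\t1001000\tchr1\t5000000\t5001000\tpromoter\tenhancer\tactive",
    # promoter anchor away from any TSS
    "chr1\t7000000\t7001000\tchr1\t1999000\t2001000\tpromoter\tpromoter\t"
  ), path)
  expect_warning(ints <- read_interactions(path, annotation = ann),
                 "overlap no annotated TSS")
  expect_equal(nrow(ints), 3)
  expect_equal(ints$genes_a[[1]], "g001")
  expect_equal(ints$genes_b[[1]], "g002")
  expect_equal(ints$enhancer_class[2], "active")
  expect_length(ints$genes_a[[3]], 0)

  # enhancer record lacking class errors
  writeLines("chr1\t999000\t1001000\tchr1\t5000000\t5001000\tpromoter\tenhancer\t",
             path)
  expect_error(read_interactions(path, annotation = ann), "enhancer_class")
})

test_that("interaction writer round-trips coordinates and kinds", {
  ann <- toy_annotation(3, spacing = 1e6)
  ints <- toy_interactions("chr1", 1e6, "chr1", 2e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(ints, path)
  back <- read_interactions(path, annotation = ann)
  expect_equal(back$start_a, ints$start_a)
  expect_equal(back$end_b, ints$end_b)
  expect_equal(back$a_kind, ints$a_kind)
})

test_that("chromatin-state and decay readers validate their domains", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("g1", "g2"),
                                  state = c("PRCa", "Active")), path)
  st <- read_chromatin_states(path)
  expect_equal(st$state, c("PRCa", "Active"))
  readr::write_tsv(tibble::tibble(gene_id = "g1", state = "Polycomb"), path)
  expect_error(read_chromatin_states(path), "unknown chromatin state")
  readr::write_tsv(tibble::tibble(gene_id = "g1", decay = -1), path)
  expect_error(read_decay_table(path), "positive")
})
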