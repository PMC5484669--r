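# small in-code fixtures shared across tests

toy_counts <- function(m, cells = paste0("c", seq_len(nrow(m))),
                       genes = paste0("g", seq_len(ncol(m)))) {
  dimnames(m) <- list(cells, genes)
  count_matrix(m)
}

# annotation with evenly spaced TSSs on one or more chromosomes
toy_annotation <- function(n, spacing = 1e5, chroms = "chr1", length = 1000) {
  per <- split(seq_len(n), rep_len(chroms, n))
  rows <- lapply(names(per), function(ch) {
    idx <- per[[ch]]
    tibble::tibble(
      gene_id = sprintf("g%03d", idx),
      chromosome = ch,
      start = seq_along(idx) * spacing,
      end = seq_along(idx) * spacing + length - 1,
      tss = seq_along(idx) * spacing,
      strand = "+",
      length = length
    )
  })
  dplyr::bind_rows(rows)
}

# interaction_set built directly (internal 1-based coordinates)
toy_interactions <- function(chr_a, pos_a, chr_b, pos_b,
                             a_kind = "promoter", b_kind = "promoter",
                             enhancer_class = NA_character_,
                             genes_a = NULL, genes_b = NULL, half = 1000) {
  n <- length(chr_a)
  df <- tibble::tibble(
    chr_a = chr_a, start_a = pos_a - half, end_a = pos_a + half,
    chr_b = chr_b, start_b = pos_b - half, end_b = pos_b + half,
    a_kind = rep_len(a_kind, n), b_kind = rep_len(b_kind, n),
    enhancer_class = rep_len(enhancer_class, n),
    genes_a = genes_a %||% rep(list(character(0)), n),
    genes_b = genes_b %||% rep(list(character(0)), n)
  )
  class(df) <- c("interaction_set", class(df))
  df
}

`%||%` <- rlang::`%||%`

planted_dm_genome <- function(n = 600, n_runs = 10, run_len = 5, shift = 2,
                              seed = 1, chroms = paste0("chr", 1:3)) {
  set.seed(seed)
  ann <- toy_annotation(n, spacing = 1e5, chroms = chroms)
  dm <- rnorm(n)
  ord <- order(ann$chromosome, ann$tss)
  taken <- rep(FALSE, n)
  runs <- list()
  while (length(runs) < n_runs) {
    st <- sample.int(n - run_len + 1, 1)
    idx <- ord[st:(st + run_len - 1)]
    if (any(taken[idx]) ||
        length(unique(ann$chromosome[idx])) > 1) next
    taken[idx] <- TRUE
    dm[idx] <- dm[idx] + shift
    runs[[length(runs) + 1]] <- ann$gene_id[idx]
  }
  list(tab = tibble::tibble(gene_id = ann$gene_id, dm = dm),
       ann = ann, runs = runs)
}

# a gene universe plus a contact list with planted within-set density
planted_contacts <- function(n_genes = 2000, set_size = 150, boost = 3,
                             base_pairs = 20000, seed = 1) {
  set.seed(seed)
  ann <- toy_annotation(n_genes, spacing = 3e6, chroms = paste0("chr", 1:4))
  gene_set <- sample(ann$gene_id, set_size)
  ia <- sample(n_genes, base_pairs * boost, replace = TRUE)
  ib <- sample(n_genes, base_pairs * boost, replace = TRUE)
  ok <- ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  inset <- ann$gene_id[ia] %in% gene_set & ann$gene_id[ib] %in% gene_set
  keep <- inset | (runif(length(ia)) < 1 / boost)
  ia <- ia[keep]; ib <- ib[keep]
  ints <- toy_interactions(
    chr_a = ann$chromosome[ia], pos_a = ann$tss[ia],
    chr_b = ann$chromosome[ib], pos_b = ann$tss[ib],
    genes_a = as.list(ann$gene_id[ia]), genes_b = as.list(ann$gene_id[ib])
  )
  list(ann = ann, set = gene_set, ints = ints)
}
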