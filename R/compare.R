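# Per-class comparison of two conditions (e.g. untreated Ring1A-KO vs
# tamoxifen-treated Ring1A/B-dKO).

#' Per-class shifts between two conditions
#'
#' Computes per-gene changes between a reference condition and a perturbed
#' one — log2 fold change of mean normalized expression (with a pseudocount),
#' and differences in DM, bimodality index and burst frequency where those
#' columns are present in both inputs — and tests, for each class pair,
#' whether the shift distributions differ: a two-tailed Wilcoxon rank-sum
#' test on `delta_mean`, and one-tailed Welch t-tests on `delta_dm`,
#' `delta_bi` and `delta_burst_freq` (direction: the first class of the pair
#' shifts lower, e.g. a larger noise decrease at PRCa than at Active).
#'
#' DM (and any other dataset-relative statistic) should be computed within
#' each condition separately before calling this function; the deltas are
#' plain differences of the per-condition values.
#'
#' @param ref,perturbed per-gene tibbles with `gene_id`, `mean` and
#'   optionally `dm`, `bimodality_index`, `burst_freq`.
#' @param states chromatin-state table (`gene_id`, `state`).
#' @param class_pairs list of 2-vectors of classes to compare; default
#'   PRCr-PRCa, PRCa-Active, PRCr-Active.
#' @param pseudocount added to means before the log2 ratio (default 1).
#' @param log2_scale use log2 fold change (default); `FALSE` uses the plain
#'   difference of means.
#' @param min_genes classes with fewer genes are skipped with a warning.
#' @return A list with `per_gene` (tibble of deltas, restricted to genes
#'   present in both conditions) and `tests` (tibble: `metric`, `class_a`,
#'   `class_b`, `n_a`, `n_b`, `median_a`, `median_b`, `p`, `alternative`).
#' @export
class_shift_tests <- function(ref, perturbed, states,
                              class_pairs = list(c("PRCr", "PRCa"),
                                                 c("PRCa", "Active"),
                                                 c("PRCr", "Active")),
                              pseudocount = 1, log2_scale = TRUE,
                              min_genes = 10) {
  shared <- intersect(ref$gene_id, perturbed$gene_id)
  if (length(shared) == 0) abort("no shared genes between conditions")
  r <- ref[match(shared, ref$gene_id), ]
  k <- perturbed[match(shared, perturbed$gene_id), ]
  per_gene <- tibble(gene_id = shared)
  per_gene$delta_mean <- if (log2_scale) {
    log2((k$mean + pseudocount) / (r$mean + pseudocount))
  } else k$mean - r$mean
  for (col in c("dm", "bimodality_index", "burst_freq")) {
    if (col %in% names(r) && col %in% names(k)) {
      per_gene[[paste0("delta_", sub("bimodality_index", "bi", col))]] <-
        k[[col]] - r[[col]]
    }
  }
  per_gene <- left_join(per_gene, states, by = "gene_id")

  metrics <- intersect(c("delta_mean", "delta_dm", "delta_bi", "delta_burst_freq"),
                       names(per_gene))
  rows <- list()
  for (pair in class_pairs) {
    a <- per_gene[per_gene$state %in% pair[1], ]
    b <- per_gene[per_gene$state %in% pair[2], ]
    for (m in metrics) {
      xa <- a[[m]][is.finite(a[[m]])]
      xb <- b[[m]][is.finite(b[[m]])]
      if (length(xa) < min_genes || length(xb) < min_genes) {
        warn(sprintf("skipping %s %s vs %s: fewer than %d genes",
                     m, pair[1], pair[2], min_genes))
        next
      }
      if (m == "delta_mean") {
        p <- wilcox.test(xa, xb)$p.value
        alt <- "two.sided"
      } else {
        p <- t.test(xa, xb, alternative = "less")$p.value
        alt <- "less"
      }
      rows[[length(rows) + 1]] <- tibble(
        metric = m, class_a = pair[1], class_b = pair[2],
        n_a = length(xa), n_b = length(xb),
        median_a = median(xa), median_b = median(xb),
        p = p, alternative = alt
      )
    }
  }
  list(per_gene = per_gene, tests = bind_rows(rows))
}
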