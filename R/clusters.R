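# Chromosomal-position analyses of expression noise.

# join a dm table with TSS positions, keeping only genes with both
dm_with_positions <- function(dm_table, annotation) {
  out <- inner_join(dm_table[, c("gene_id", "dm",
                                 intersect("mean", names(dm_table)))],
                    annotation[, c("gene_id", "chromosome", "tss")],
                    by = "gene_id")
  if (nrow(out) == 0) abort("no genes shared between dm table and annotation")
  arrange(out, .data$chromosome, .data$tss, .data$gene_id)
}

# index of neighbours within +-window bp of each gene's TSS (same chromosome,
# focal gene excluded); positions are fixed, so this is computed once and
# reused across DM randomizations
neighbor_index <- function(pos, window) {
  by_chr <- split(seq_len(nrow(pos)), pos$chromosome)
  out <- vector("list", nrow(pos))
  for (idx in by_chr) {
    tss <- pos$tss[idx]
    lo <- findInterval(tss - window, tss, left.open = TRUE) + 1
    hi <- findInterval(tss + window, tss)
    for (k in seq_along(idx)) {
      nb <- idx[seq.int(lo[k], hi[k])]
      out[[idx[k]]] <- nb[nb != idx[k]]
    }
  }
  out
}

#' Neighborhood noise test
#'
#' Are genes flanking noisy genes themselves noisier than genes flanking
#' stable genes? Genes are ranked by DM; the top `top_frac` are "noisy" and
#' the bottom `top_frac` "stable". For each neighborhood size W, the DM
#' values of all genes within +-W bp of each noisy focal gene (focal
#' excluded) are pooled and compared with the stable-focal pool by a
#' one-tailed Wilcoxon rank sum test. A mean-expression control (two-tailed
#' Wilcoxon on the flanking mean expressions) is reported alongside. As a
#' control band, the DM values are reassigned randomly over the fixed gene
#' positions `n_random_genomes` times and the test repeated, yielding the
#' 2.5% / 97.5% quantiles of the randomized p-values.
#'
#' @param dm_table tibble with `gene_id`, `dm` and (for the control) `mean`.
#' @param annotation annotation tibble with `gene_id`, `chromosome`, `tss`.
#' @param window_bp vector of neighborhood half-widths in bp (default a grid
#'   from 20 kb to 0.5 Mb around the 50 kb headline size).
#' @param top_frac fraction declared noisy / stable (default 0.20).
#' @param n_random_genomes randomized genomes for the control band.
#' @param seed optional seed for the randomizations.
#' @return A tibble of class `neighborhood_noise`: `window_bp`, `p_noise`,
#'   `p_mean_control`, `rand_lo`, `rand_hi`, `n_noisy_pool`, `n_stable_pool`.
#'   Window sizes with an empty pool are skipped with a warning.
#' @export
neighborhood_noise_test <- function(dm_table, annotation,
                                    window_bp = c(2e4, 5e4, 1e5, 2e5, 5e5),
                                    top_frac = 0.20, n_random_genomes = 100,
                                    seed = NULL) {
  pos <- dm_with_positions(dm_table, annotation)
  n <- nrow(pos)
  n_top <- floor(top_frac * n)
  if (n_top < 1) abort("too few genes for the chosen top_frac")
  has_mean <- "mean" %in% names(pos)

  one_genome <- function(dmv) {
    o <- order(dmv, decreasing = TRUE)
    list(noisy = o[seq_len(n_top)], stable = rev(o)[seq_len(n_top)])
  }

  rows <- list()
  for (w in window_bp) {
    nbr <- neighbor_index(pos, w)
    pool_of <- function(focal, values) values[unlist(nbr[focal], use.names = FALSE)]
    sets <- one_genome(pos$dm)
    noisy_pool <- pool_of(sets$noisy, pos$dm)
    stable_pool <- pool_of(sets$stable, pos$dm)
    if (length(noisy_pool) == 0 || length(stable_pool) == 0) {
      warn(sprintf("empty neighbor pool at window %g bp; skipped", w))
      next
    }
    p_noise <- wilcox.test(noisy_pool, stable_pool,
                           alternative = "greater")$p.value
    p_mean <- if (has_mean) {
      wilcox.test(pool_of(sets$noisy, pos$mean),
                  pool_of(sets$stable, pos$mean))$p.value
    } else NA_real_
    rand_p <- local_seed(seed, {
      vapply(seq_len(n_random_genomes), function(i) {
        dms <- sample(pos$dm)
        ss <- one_genome(dms)
        np <- pool_of(ss$noisy, dms); sp <- pool_of(ss$stable, dms)
        if (length(np) == 0 || length(sp) == 0) return(NA_real_)
        wilcox.test(np, sp, alternative = "greater")$p.value
      }, numeric(1))
    })
    rows[[length(rows) + 1]] <- tibble(
      window_bp = w, p_noise = p_noise, p_mean_control = p_mean,
      rand_lo = quantile(rand_p, 0.025, na.rm = TRUE, names = FALSE),
      rand_hi = quantile(rand_p, 0.975, na.rm = TRUE, names = FALSE),
      n_noisy_pool = length(noisy_pool), n_stable_pool = length(stable_pool)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("neighborhood_noise", class(out))
  out
}

# window noise score: sum of rolling means of consecutive DM pairs, i.e.
# (d1+d2)/2 + (d2+d3)/2 + ... — inner genes carry double weight
window_score <- function(dm) {
  w <- length(dm)
  sum((dm[-w] + dm[-1]) / 2)
}

#' Call noisy and stable gene clusters by a sliding window
#'
#' Genes with valid DM are ordered by TSS along each chromosome and scanned
#' with a window of `window_size` genes (shifting by one gene). Windows whose
#' first-to-last TSS span exceeds `(window_size - 1) * span_cap` are ignored.
#' Each window is scored by summing rolling means of consecutive DM pairs.
#' The null distribution is built from `n_null` draws of `window_size` DM
#' values sampled without replacement from the genome-wide pool of valid DM
#' values; a window is noisy when its score exceeds the `1 - q` null quantile
#' and stable when below the `q` quantile (strict inequalities). Overlapping
#' significant windows of the same label are merged into clusters.
#'
#' @param dm_table tibble with `gene_id`, `dm`.
#' @param annotation annotation tibble with `gene_id`, `chromosome`, `tss`.
#' @param window_size genes per window (default 4).
#' @param span_cap maximum TSS gap budget per inter-gene step, bp
#'   (default 0.5 Mb).
#' @param n_null null draws (default 1e5).
#' @param q tail probability per side (default 0.025).
#' @param seed optional seed for the null draws.
#' @return A tibble of class `noise_clusters`: `chromosome`, `start`, `end`
#'   (TSS bounds), `label` (`noisy`/`stable`), `n_genes`, `genes`
#'   (list-column). Attributes `windows` (all admissible windows with scores
#'   and calls) and `null_quantiles`.
#' @export
call_noise_clusters <- function(dm_table, annotation, window_size = 4,
                                span_cap = 5e5, n_null = 1e5, q = 0.025,
                                seed = NULL) {
  pos <- dm_with_positions(dm_table, annotation)
  w <- window_size
  pool <- pos$dm
  if (length(pool) < w) abort("fewer valid-DM genes than the window size")
  null_scores <- local_seed(seed, {
    vapply(seq_len(n_null), function(i) window_score(pool[sample.int(length(pool), w)]),
           numeric(1))
  })
  hi <- quantile(null_scores, 1 - q, names = FALSE)
  lo <- quantile(null_scores, q, names = FALSE)

  win_rows <- list()
  for (chr in unique(pos$chromosome)) {
    p <- pos[pos$chromosome == chr, ]
    if (nrow(p) < w) next
    for (i in seq_len(nrow(p) - w + 1)) {
      j <- i + w - 1
      span <- p$tss[j] - p$tss[i]
      if (span > (w - 1) * span_cap) next
      sc <- window_score(p$dm[i:j])
      lab <- if (sc > hi) "noisy" else if (sc < lo) "stable" else NA_character_
      win_rows[[length(win_rows) + 1]] <- tibble(
        chromosome = chr, first = i, last = j,
        start = p$tss[i], end = p$tss[j], span = span, score = sc,
        label = lab, genes = list(p$gene_id[i:j])
      )
    }
  }
  windows <- bind_rows(win_rows)

  clusters <- list()
  if (nrow(windows) > 0) {
    sig <- windows[!is.na(windows$label), ]
    for (key in unique(paste(sig$chromosome, sig$label))) {
      ss <- sig[paste(sig$chromosome, sig$label) == key, ]
      ss <- arrange(ss, .data$first)
      cur_first <- ss$first[1]; cur_last <- ss$last[1]; members <- ss$genes[[1]]
      flush <- function(first, last, members, row) {
        tibble(chromosome = row$chromosome[1],
               start = min(row$start), end = max(row$end),
               label = row$label[1], n_genes = length(members),
               genes = list(members))
      }
      start_i <- 1
      for (r in seq_len(nrow(ss))[-1]) {
        if (ss$first[r] <= cur_last) {  # shares at least one gene
          cur_last <- max(cur_last, ss$last[r])
          members <- union(members, ss$genes[[r]])
        } else {
          clusters[[length(clusters) + 1]] <-
            flush(cur_first, cur_last, members, ss[start_i:(r - 1), ])
          cur_first <- ss$first[r]; cur_last <- ss$last[r]
          members <- ss$genes[[r]]; start_i <- r
        }
      }
      clusters[[length(clusters) + 1]] <-
        flush(cur_first, cur_last, members, ss[start_i:nrow(ss), ])
    }
  }
  out <- if (length(clusters)) bind_rows(clusters) else
    tibble(chromosome = character(), start = numeric(), end = numeric(),
           label = character(), n_genes = integer(), genes = list())
  out <- arrange(out, .data$chromosome, .data$start)
  attr(out, "windows") <- windows
  attr(out, "null_quantiles") <- c(lo = lo, hi = hi)
  class(out) <- c("noise_clusters", class(out))
  out
}

#' Chromatin-mark enrichment in noise clusters
#'
#' For each mark (or chromatin-state indicator) and each cluster label, a
#' 2x2 table of background genes cross-classified by cluster membership and
#' mark presence is tested with a two-tailed Fisher's exact test.
#'
#' @param clusters result of [call_noise_clusters()].
#' @param marks tibble with `gene_id` plus one logical column per mark, or a
#'   chromatin-state table (`gene_id`, `state`), in which case one indicator
#'   per state is built. Its gene universe is the background.
#' @return A tibble: `label`, `mark`, `in_with`, `in_without`, `out_with`,
#'   `out_without`, `odds_ratio`, `p`.
#' @export
cluster_mark_enrichment <- function(clusters, marks) {
  if ("state" %in% names(marks)) {
    marks <- tibble(gene_id = marks$gene_id) |>
      bind_cols(as_tibble(sapply(unique(marks$state),
                                 function(s) marks$state == s,
                                 simplify = FALSE)))
  }
  mark_cols <- setdiff(names(marks), "gene_id")
  rows <- list()
  for (lab in c("noisy", "stable")) {
    members <- unique(unlist(clusters$genes[clusters$label == lab]))
    in_cluster <- marks$gene_id %in% members
    for (mk in mark_cols) {
      with_mark <- as.logical(marks[[mk]])
      a <- sum(in_cluster & with_mark); b <- sum(in_cluster & !with_mark)
      c_ <- sum(!in_cluster & with_mark); d <- sum(!in_cluster & !with_mark)
      tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warn(sprintf("empty margin for %s in %s clusters; p set to 1", mk, lab))
        or <- NA_real_; p <- 1
      } else {
        ft <- fisher.test(tab)
        or <- unname(ft$estimate); p <- ft$p.value
      }
      rows[[length(rows) + 1]] <- tibble(
        label = lab, mark = mk, in_with = a, in_without = b,
        out_with = c_, out_without = d, odds_ratio = or, p = p
      )
    }
  }
  bind_rows(rows)
}

#' Noise of active genes versus number of noisy flanking genes
#'
#' Groups `focal_genes` (typically active genes) by the number of noisy genes
#' within +-`window_bp` of their TSS and reports the median DM per group plus
#' a Spearman rank-trend test of DM against flanker count.
#'
#' @param dm_table tibble with `gene_id`, `dm`.
#' @param annotation annotation tibble with `gene_id`, `chromosome`, `tss`.
#' @param focal_genes gene ids to group (e.g. the Active class).
#' @param noisy_genes gene ids counted as noisy flankers.
#' @param window_bp neighborhood half-width (default 50 kb).
#' @return A list with `groups` (tibble: `n_noisy_flankers`, `n_genes`,
#'   `median_dm`), `trend_rho` and `trend_p` (NA when fewer than two distinct
#'   flanker counts exist).
#' @export
flanking_variability_trend <- function(dm_table, annotation, focal_genes,
                                       noisy_genes, window_bp = 5e4) {
  pos <- dm_with_positions(dm_table, annotation)
  nbr <- neighbor_index(pos, window_bp)
  is_noisy <- pos$gene_id %in% noisy_genes
  focal_idx <- which(pos$gene_id %in% focal_genes)
  counts <- vapply(focal_idx, function(i) sum(is_noisy[nbr[[i]]]), numeric(1))
  df <- tibble(gene_id = pos$gene_id[focal_idx], dm = pos$dm[focal_idx],
               n_noisy_flankers = counts)
  groups <- df |>
    group_by(.data$n_noisy_flankers) |>
    summarise(n_genes = n(), median_dm = median(.data$dm), .groups = "drop")
  if (length(unique(counts)) < 2) {
    return(list(groups = groups, per_gene = df,
                trend_rho = NA_real_, trend_p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(df$n_noisy_flankers, df$dm, method = "spearman")
  )
  list(groups = groups, per_gene = df,
       trend_rho = unname(ct$estimate), trend_p = ct$p.value)
}
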