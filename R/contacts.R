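# Promoter-contact enrichment and enhancer-link analyses.

anchor_mid <- function(start, end) (start + end) / 2

#' Remove short-range intrachromosomal contacts
#'
#' Intrachromosomal interactions whose anchor midpoints are separated by less
#' than `min_sep` bp are dropped; interchromosomal interactions are retained.
#' Applying the filter twice equals applying it once.
#'
#' @param interactions an `interaction_set` tibble (see [read_interactions()]).
#' @param min_sep minimum separation in bp (default 10 Mb).
#' @return The filtered `interaction_set`.
#' @export
filter_long_range <- function(interactions, min_sep = 1e7) {
  sep <- abs(anchor_mid(interactions$start_a, interactions$end_a) -
               anchor_mid(interactions$start_b, interactions$end_b))
  keep <- interactions$chr_a != interactions$chr_b | sep >= min_sep
  interactions[keep, ]
}

# expand promoter-promoter interactions into unordered gene pairs; a
# multi-gene anchor contributes once per gene pair
contact_gene_pairs <- function(interactions) {
  pp <- interactions[interactions$a_kind == "promoter" &
                       interactions$b_kind == "promoter", ]
  if (nrow(pp) == 0) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  rows <- map(seq_len(nrow(pp)), function(i) {
    ga <- pp$genes_a[[i]]; gb <- pp$genes_b[[i]]
    if (length(ga) == 0 || length(gb) == 0) return(NULL)
    pairs <- expand.grid(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    if (nrow(pairs) == 0) return(NULL)
    swap <- pairs$gene_a > pairs$gene_b
    tmp <- pairs$gene_a[swap]
    pairs$gene_a[swap] <- pairs$gene_b[swap]
    pairs$gene_b[swap] <- tmp
    unique(pairs)
  })
  as_tibble(bind_rows(rows))
}

# log-spaced distance-bin labels for pairwise TSS distances within a gene
# set; interchromosomal pairs get their own bin
pairwise_distance_bins <- function(tss, chrom, breaks) {
  n <- length(tss)
  if (n < 2) return(integer(0))
  idx <- utils::combn(n, 2)
  same <- chrom[idx[1, ]] == chrom[idx[2, ]]
  d <- abs(tss[idx[1, ]] - tss[idx[2, ]])
  bin <- findInterval(d, breaks)
  bin[!same] <- length(breaks) + 1L  # interchromosomal bin
  bin
}

bin_histogram <- function(bins, n_bins) {
  tabulate(bins, nbins = n_bins) / max(length(bins), 1)
}

#' Contact enrichment of a promoter set
#'
#' Counts long-range promoter-promoter contacts with both ends in `gene_set`
#' and compares with random promoter sets of the same size drawn from
#' `annotation` (restricted to `universe` when given) to match the
#' experimental set's pairwise TSS-distance distribution: distances are
#' binned on a log grid (interchromosomal pairs form their own bin) and each
#' random set — seeded per chromosome with the experimental per-chromosome
#' composition — is refined by greedy same-chromosome swaps until its bin
#' histogram is within `tol` (L1) of the experimental one or `max_swaps` is
#' reached. Enrichment = observed / mean(control counts), computed per
#' control group; the mean and standard deviation over `n_groups` independent
#' groups are reported.
#'
#' @param interactions a long-range-filtered `interaction_set`.
#' @param gene_set character vector of gene ids (the experimental promoter
#'   set).
#' @param annotation annotation tibble (`gene_id`, `chromosome`, `tss`).
#' @param universe optional gene-id vector delimiting the promoters random
#'   sets may draw from (default: all annotated genes).
#' @param n_sets random sets per control group (default 100).
#' @param n_groups independent control groups (default 3).
#' @param tol L1 histogram tolerance (default 0.05).
#' @param max_swaps refinement budget per random set (default 200).
#' @param seed optional seed.
#' @return An object of class `contact_enrichment`: `observed`,
#'   `control_means` (one per group), `enrichment`, `enrichment_mean`,
#'   `enrichment_sd`, `per_set` (tibble with group, count, enrichment and the
#'   Kolmogorov-Smirnov distance between intrachromosomal distance
#'   distributions), `n_sets`, `n_groups`.
#' @export
contact_enrichment <- function(interactions, gene_set, annotation,
                               universe = NULL, n_sets = 100, n_groups = 3,
                               tol = 0.05, max_swaps = 200, seed = NULL) {
  ann <- annotation
  if (!is.null(universe)) ann <- ann[ann$gene_id %in% union(universe, gene_set), ]
  gene_set <- intersect(gene_set, ann$gene_id)
  if (length(gene_set) < 2) abort("gene_set needs at least two annotated genes")
  pairs <- contact_gene_pairs(interactions)
  count_in <- function(ids) {
    sum(pairs$gene_a %in% ids & pairs$gene_b %in% ids)
  }
  observed <- count_in(gene_set)

  exp_rows <- match(gene_set, ann$gene_id)
  breaks <- c(0, 10^seq(5, 9, by = 0.5))
  n_bins <- length(breaks) + 1L
  exp_bins <- pairwise_distance_bins(ann$tss[exp_rows], ann$chromosome[exp_rows],
                                     breaks)
  h_exp <- bin_histogram(exp_bins, n_bins)
  exp_intra_d <- {
    idx <- utils::combn(length(exp_rows), 2)
    same <- ann$chromosome[exp_rows][idx[1, ]] == ann$chromosome[exp_rows][idx[2, ]]
    abs(ann$tss[exp_rows][idx[1, ]] - ann$tss[exp_rows][idx[2, ]])[same]
  }
  chr_comp <- table(ann$chromosome[exp_rows])
  by_chr <- split(seq_len(nrow(ann)), ann$chromosome)

  draw_set <- function() {
    sel <- unlist(lapply(names(chr_comp), function(ch) {
      cand <- by_chr[[ch]]
      if (length(cand) < chr_comp[[ch]]) {
        warn(sprintf("chromosome %s has too few promoters; bin widened to all chromosomes", ch))
        return(sample(seq_len(nrow(ann)), chr_comp[[ch]]))
      }
      cand[sample.int(length(cand), chr_comp[[ch]])]
    }), use.names = FALSE)
    # greedy same-chromosome swaps toward the experimental distance histogram
    h <- bin_histogram(pairwise_distance_bins(ann$tss[sel], ann$chromosome[sel],
                                              breaks), n_bins)
    obj <- sum(abs(h - h_exp))
    for (it in seq_len(max_swaps)) {
      if (obj <= tol) break
      i <- sample.int(length(sel), 1)
      ch <- ann$chromosome[sel[i]]
      cand <- setdiff(by_chr[[ch]], sel)
      if (length(cand) == 0) next
      repl <- cand[sample.int(length(cand), 1)]
      new_sel <- sel; new_sel[i] <- repl
      h_new <- bin_histogram(
        pairwise_distance_bins(ann$tss[new_sel], ann$chromosome[new_sel], breaks),
        n_bins)
      obj_new <- sum(abs(h_new - h_exp))
      if (obj_new < obj) { sel <- new_sel; obj <- obj_new }
    }
    sel
  }

  per_set <- local_seed(seed, {
    rows <- list()
    for (g in seq_len(n_groups)) {
      for (k in seq_len(n_sets)) {
        sel <- draw_set()
        ids <- ann$gene_id[sel]
        cnt <- count_in(ids)
        idx <- utils::combn(length(sel), 2)
        same <- ann$chromosome[sel][idx[1, ]] == ann$chromosome[sel][idx[2, ]]
        dd <- abs(ann$tss[sel][idx[1, ]] - ann$tss[sel][idx[2, ]])[same]
        ks <- if (length(dd) > 0 && length(exp_intra_d) > 0) {
          suppressWarnings(unname(ks.test(dd, exp_intra_d)$statistic))
        } else NA_real_
        rows[[length(rows) + 1]] <- tibble(group = g, set = k, count = cnt,
                                           ks_distance = ks)
      }
    }
    bind_rows(rows)
  })
  control_means <- per_set |>
    group_by(.data$group) |>
    summarise(mean_count = mean(.data$count), .groups = "drop")
  enr_groups <- observed / pmax(control_means$mean_count, .Machine$double.eps)
  per_set$enrichment <- observed / pmax(per_set$count, .Machine$double.eps)
  structure(
    list(
      observed = observed,
      control_means = control_means$mean_count,
      enrichment = observed / max(mean(per_set$count), .Machine$double.eps),
      enrichment_by_group = enr_groups,
      enrichment_mean = mean(enr_groups),
      enrichment_sd = sd(enr_groups),
      per_set = per_set, n_sets = n_sets, n_groups = n_groups,
      n_genes = length(gene_set)
    ),
    class = "contact_enrichment"
  )
}

#' @export
print.contact_enrichment <- function(x, ...) {
  cat(sprintf(
    "<contact_enrichment> observed %d contacts in %d genes; enrichment %.2f (mean %.2f +- %.2f over %d groups of %d sets)\n",
    x$observed, x$n_genes, x$enrichment, x$enrichment_mean, x$enrichment_sd,
    x$n_groups, x$n_sets))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.contact_enrichment <- function(x, ...) {
  tibble(observed = x$observed, enrichment = x$enrichment,
         enrichment_mean = x$enrichment_mean, enrichment_sd = x$enrichment_sd,
         n_genes = x$n_genes, n_sets = x$n_sets, n_groups = x$n_groups)
}

#' Compare the contact enrichment of two gene sets
#'
#' One-tailed Welch t-test on per-set enrichment values.
#'
#' @param a,b `contact_enrichment` objects.
#' @param alternative passed to [t.test()]; `"greater"` tests whether `a` is
#'   more enriched than `b`.
#' @return A tibble with the t statistic and p-value.
#' @export
compare_contact_enrichment <- function(a, b, alternative = "greater") {
  tt <- t.test(a$per_set$enrichment, b$per_set$enrichment,
               alternative = alternative)
  tibble(statistic = unname(tt$statistic), p = tt$p.value,
         mean_a = mean(a$per_set$enrichment), mean_b = mean(b$per_set$enrichment),
         alternative = alternative)
}

#' Promoter-class contact preference
#'
#' Tabulates promoter-promoter contacts by unordered chromatin-class pair
#' and, for each class, tests with a two-tailed Fisher's exact test whether
#' contact ends of that class prefer partners of the same class (each contact
#' is counted in both orientations for the collapse).
#'
#' @param interactions a long-range-filtered `interaction_set`.
#' @param states chromatin-state table (`gene_id`, `state`).
#' @return A list with `pair_counts` (tibble: `class_a`, `class_b`, `n`) and
#'   `preference` (tibble: `class`, `odds_ratio`, `p`; `NA` when the table is
#'   degenerate).
#' @export
promoter_class_preference <- function(interactions, states) {
  pairs <- contact_gene_pairs(interactions)
  cls <- setNames(states$state, states$gene_id)
  pairs$class_a <- unname(cls[pairs$gene_a])
  pairs$class_b <- unname(cls[pairs$gene_b])
  pairs <- pairs[complete.cases(pairs[, c("class_a", "class_b")]), ]
  if (nrow(pairs) == 0) {
    return(list(pair_counts = tibble(class_a = character(),
                                     class_b = character(), n = integer()),
                preference = tibble(class = character(),
                                    odds_ratio = numeric(), p = numeric())))
  }
  key <- pmin(pairs$class_a, pairs$class_b)
  key2 <- pmax(pairs$class_a, pairs$class_b)
  pair_counts <- tibble(class_a = key, class_b = key2) |>
    count(.data$class_a, .data$class_b, name = "n")
  # both orientations: each contact yields two (focal end, partner) records
  focal <- c(pairs$class_a, pairs$class_b)
  partner <- c(pairs$class_b, pairs$class_a)
  pref <- map(sort(unique(focal)), function(cl) {
    a <- sum(focal == cl & partner == cl)
    b <- sum(focal == cl & partner != cl)
    c_ <- sum(focal != cl & partner == cl)
    d <- sum(focal != cl & partner != cl)
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || nrow(pairs) < 2) {
      return(tibble(class = cl, odds_ratio = NA_real_, p = NA_real_))
    }
    ft <- fisher.test(tab)
    tibble(class = cl, odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  list(pair_counts = pair_counts, preference = bind_rows(pref))
}

#' Per-gene enhancer-contact counts
#'
#' Counts, for each gene, its promoter-enhancer interactions by enhancer
#' class.
#'
#' @param interactions an `interaction_set` (filtering is the caller's
#'   choice; enhancer contacts are usually not distance-filtered).
#' @param genes gene-id universe; genes without links get zero counts.
#' @return A tibble: `gene_id`, `n_active`, `n_intermediate`, `n_poised`.
#' @export
enhancer_link_summary <- function(interactions, genes) {
  pe <- interactions[xor(interactions$a_kind == "enhancer",
                         interactions$b_kind == "enhancer"), ]
  out <- tibble(gene_id = genes, n_active = 0L, n_intermediate = 0L,
                n_poised = 0L)
  if (nrow(pe) > 0) {
    gene_lists <- lapply(seq_len(nrow(pe)), function(i) {
      if (pe$a_kind[i] == "promoter") pe$genes_a[[i]] else pe$genes_b[[i]]
    })
    long <- tibble(
      gene_id = unlist(gene_lists),
      class = rep(pe$enhancer_class, lengths(gene_lists))
    ) |>
      count(.data$gene_id, .data$class)
    for (cl in c("active", "intermediate", "poised")) {
      sub <- long[long$class == cl, ]
      col <- paste0("n_", cl)
      idx <- match(sub$gene_id, out$gene_id)
      out[[col]][idx[!is.na(idx)]] <- sub$n[!is.na(idx)]
    }
  }
  out
}

#' Enhancer contacts and expression noise
#'
#' Two analyses: (i) Wilcoxon rank-sum comparisons of active- and
#' poised-enhancer contact counts between the PRCa and PRCr classes;
#' (ii) PRCa genes are split into low/high active-enhancer-contact groups
#' (0 versus >= 1 when the count distribution is zero-inflated, otherwise a
#' median split) and their DM compared by a two-tailed Wilcoxon test, with
#' the same test on mean expression reported as a control.
#'
#' @param links tibble from [enhancer_link_summary()].
#' @param noise tibble with `gene_id`, `dm`, `mean`.
#' @param states chromatin-state table (`gene_id`, `state`).
#' @param split `"auto"` (default), `"zero"` (0 vs >= 1) or `"median"`.
#' @return A list with `class_tests` (tibble comparing PRCa vs PRCr counts),
#'   `noise_test` (tibble: split rule, group sizes, median DM per group, DM
#'   p-value and the mean-expression control p-value).
#' @export
enhancer_noise_association <- function(links, noise, states,
                                       split = c("auto", "zero", "median")) {
  split <- match.arg(split)
  df <- links |>
    inner_join(states, by = "gene_id") |>
    left_join(noise[, c("gene_id", "dm", "mean")], by = "gene_id")
  prca <- df[df$state == "PRCa" & !is.na(df$dm), ]
  prcr <- df[df$state == "PRCr", ]
  if (nrow(prca) == 0) abort("no PRCa genes with DM values")
  class_tests <- bind_rows(
    tibble(
      comparison = "active_enhancer_contacts_PRCa_vs_PRCr",
      p = wilcox.test(prca$n_active, prcr$n_active)$p.value,
      median_prca = median(prca$n_active), median_prcr = median(prcr$n_active)
    ),
    tibble(
      comparison = "poised_enhancer_contacts_PRCa_vs_PRCr",
      p = wilcox.test(prca$n_poised, prcr$n_poised)$p.value,
      median_prca = median(prca$n_poised), median_prcr = median(prcr$n_poised)
    )
  )
  rule <- switch(split,
    zero = "zero",
    median = "median",
    auto = if (mean(prca$n_active == 0) > 0.5) "zero" else "median"
  )
  thr <- if (rule == "zero") 1 else median(prca$n_active)
  low <- prca[prca$n_active < thr, ]
  high <- prca[prca$n_active >= thr, ]
  if (rule == "median" && thr == min(prca$n_active)) {
    # all-equal guard: median split collapses; fall back to zero split
    rule <- "zero"; thr <- 1
    low <- prca[prca$n_active < thr, ]
    high <- prca[prca$n_active >= thr, ]
  }
  if (nrow(low) == 0 || nrow(high) == 0) {
    abort(sprintf("empty group after split at threshold %g", thr))
  }
  noise_test <- tibble(
    split = rule, threshold = thr, n_low = nrow(low), n_high = nrow(high),
    median_dm_low = median(low$dm), median_dm_high = median(high$dm),
    p_dm = wilcox.test(low$dm, high$dm)$p.value,
    p_mean_control = wilcox.test(low$mean, high$mean)$p.value
  )
  list(class_tests = class_tests, noise_test = noise_test)
}
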