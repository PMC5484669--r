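# Linear-genome nearest-neighbour proximity between gene classes.

# nearest |TSS - TSS| distance from each query position to a sorted set
nn_dist_to <- function(query, ref_sorted) {
  i <- findInterval(query, ref_sorted)
  lo <- pmax(i, 1); hi <- pmin(i + 1, length(ref_sorted))
  pmin(abs(query - ref_sorted[lo]), abs(query - ref_sorted[hi]))
}

#' Nearest-neighbour TSS distances between two gene sets
#'
#' For each gene of `set_a`, the distance to the closest `set_b` TSS on the
#' same chromosome. Genes present in both sets are excluded from `set_a`
#' (with a warning); `set_a` genes on chromosomes carrying no `set_b` gene
#' are excluded (logged).
#'
#' @param annotation annotation tibble with `gene_id`, `chromosome`, `tss`.
#' @param set_a,set_b character vectors of gene ids.
#' @return A tibble: `gene_id`, `chromosome`, `distance` (bp).
#' @export
nn_distance <- function(annotation, set_a, set_b) {
  overlap <- intersect(set_a, set_b)
  if (length(overlap) > 0) {
    warn(sprintf("%d gene(s) in both sets excluded from set_a", length(overlap)))
    set_a <- setdiff(set_a, overlap)
  }
  a <- annotation[annotation$gene_id %in% set_a, ]
  b <- annotation[annotation$gene_id %in% set_b, ]
  if (nrow(a) == 0) abort("no usable genes in set_a")
  if (nrow(b) == 0) abort("set_b has no annotated genes")
  b_chr <- lapply(split(b$tss, b$chromosome), sort)
  usable <- a$chromosome %in% names(b_chr)
  if (any(!usable)) {
    inform(sprintf("%d set_a gene(s) on chromosomes without set_b genes excluded",
                   sum(!usable)))
    a <- a[usable, ]
  }
  if (nrow(a) == 0) abort("no usable genes in set_a")
  d <- numeric(nrow(a))
  for (chr in unique(a$chromosome)) {
    sel <- a$chromosome == chr
    d[sel] <- nn_dist_to(a$tss[sel], b_chr[[chr]])
  }
  tibble(gene_id = a$gene_id, chromosome = a$chromosome, distance = d)
}

#' Proximity test between gene classes with a resampling null
#'
#' Tests whether `set_a` genes lie closer to `set_b` genes than expected by
#' chance. The observed statistic is the median (and mean) nearest-neighbour
#' TSS distance from `set_a` to `set_b`. The null resamples `|set_a|` genes
#' from `background`, excluding `set_b` genes and genes on chromosomes where
#' `set_b` is absent, and recomputes both statistics `n_resamples` times.
#' Empirical p-values use the add-one convention
#' `p = (1 + #{null <= observed}) / (1 + n_resamples)` for the
#' "closer than expected" direction, so the smallest attainable p is
#' `1 / (n_resamples + 1)`.
#'
#' @param annotation annotation tibble with `gene_id`, `chromosome`, `tss`.
#' @param set_a,set_b gene-id vectors (focal and target classes).
#' @param background gene-id vector the null draws from (e.g. the union of
#'   all expressed, classified genes).
#' @param n_resamples number of null resamples (default 10000).
#' @param seed optional seed.
#' @return An object of class `proximity_result`: `observed_median`,
#'   `observed_mean`, `null_medians`, `null_means`, `p_median`, `p_mean`,
#'   `n_resamples`, `n_a`, `excluded_chromosomes`.
#' @export
proximity_test <- function(annotation, set_a, set_b, background,
                           n_resamples = 10000, seed = NULL) {
  obs <- nn_distance(annotation, set_a, set_b)
  b_chroms <- unique(annotation$chromosome[annotation$gene_id %in% set_b])
  excluded_chr <- setdiff(unique(annotation$chromosome), b_chroms)
  pool_ids <- setdiff(background, set_b)
  pool <- annotation[annotation$gene_id %in% pool_ids &
                       annotation$chromosome %in% b_chroms, ]
  n_a <- nrow(obs)
  if (nrow(pool) < n_a) abort("background smaller than set_a after exclusions")
  # a pool gene's nearest-set_b distance is fixed: precompute once and
  # resample from the vector
  pool_d <- nn_distance(annotation, pool$gene_id, set_b)$distance
  nulls <- local_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      d <- pool_d[sample.int(length(pool_d), n_a)]
      c(median(d), mean(d))
    }, numeric(2))
  })
  obs_med <- median(obs$distance); obs_mean <- mean(obs$distance)
  res <- structure(
    list(
      observed_median = obs_med, observed_mean = obs_mean,
      null_medians = nulls[1, ], null_means = nulls[2, ],
      p_median = (1 + sum(nulls[1, ] <= obs_med)) / (1 + n_resamples),
      p_mean = (1 + sum(nulls[2, ] <= obs_mean)) / (1 + n_resamples),
      n_resamples = n_resamples, n_a = n_a,
      excluded_chromosomes = excluded_chr,
      distances = obs
    ),
    class = "proximity_result"
  )
  res
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> observed median %.0f bp (null median %.0f), p_median = %.3g; p_mean = %.3g (%d resamples, n = %d)\n",
    x$observed_median, median(x$null_medians), x$p_median, x$p_mean,
    x$n_resamples, x$n_a))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.proximity_result <- function(x, ...) {
  tibble(observed_median = x$observed_median, observed_mean = x$observed_mean,
         p_median = x$p_median, p_mean = x$p_mean,
         n_resamples = x$n_resamples, n_a = x$n_a)
}

#' @exportS3Method ggplot2::autoplot
autoplot.proximity_result <- function(object, ...) {
  df <- tibble(null_median = object$null_medians)
  ggplot(df, aes(x = .data$null_median)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_median, colour = "red",
               linetype = "dashed") +
    labs(x = "null median nearest-neighbour distance (bp)", y = "resamples",
         title = sprintf("observed median %.0f bp, empirical p = %.3g",
                         object$observed_median, object$p_median))
}
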