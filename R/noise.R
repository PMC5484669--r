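#' Per-gene mean and squared coefficient of variation
#'
#' @param counts a normalized [count_matrix()].
#' @return A tibble with columns `gene_id`, `mean`, `cv2`
#'   (`cv2 = variance / mean^2` across cells). Genes with zero mean are
#'   excluded with a warning (their CV^2 is undefined).
#' @export
compute_cv2 <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$normalized %||% counts$counts
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  out <- tibble(gene_id = counts$genes, mean = unname(mu),
                cv2 = unname(v / mu^2))
  if (any(mu == 0)) {
    warn(sprintf("%d zero-mean gene(s) excluded from CV^2", sum(mu == 0)))
    out <- out[mu > 0, ]
  }
  out
}

# running median with reflected edges; window rounded up to the next odd size
running_median <- function(x, window) {
  n <- length(x)
  k <- min(window, n)
  if (k %% 2 == 0) k <- k + 1
  if (k > n) k <- if (n %% 2 == 1) n else n - 1
  if (k <= 1) return(x)
  h <- (k - 1) / 2
  padded <- c(x[h:1], x, x[n:(n - h + 1)])
  as.numeric(stats::runmed(padded, k))[(h + 1):(h + n)]
}

#' Distance-to-median (DM) noise statistic
#'
#' A two-stage running-median correction of log10 CV^2. Stage one: genes are
#' ordered by log10 mean expression and the running median of log10 CV^2 is
#' subtracted, removing the mean-variance trend. Stage two: the stage-one
#' residuals are ordered by log10 gene length and their running median is
#' subtracted, removing residual length dependence. The result (DM) is a
#' noise score free of mean-expression and gene-length confounding; ties in
#' either ordering are broken by gene id for determinism.
#'
#' @param stats tibble with columns `gene_id`, `mean`, `cv2` (from
#'   [compute_cv2()]).
#' @param annotation annotation tibble carrying `gene_id` and `length`
#'   (see [read_gene_annotation()]); alternatively a `length` column already
#'   present in `stats` is used.
#' @param window_genes running-median window in genes (default 50).
#' @return The input tibble with columns `length` and `dm` added. Genes with
#'   non-positive mean or CV^2 are dropped (log undefined).
#' @export
compute_dm <- function(stats, annotation = NULL, window_genes = 50) {
  if (!"length" %in% names(stats)) {
    if (is.null(annotation)) abort("supply `annotation` or a `length` column")
    stats <- left_join(stats, annotation[, c("gene_id", "length")],
                       by = "gene_id")
  }
  if (anyNA(stats$length)) abort("missing gene length(s) for DM")
  ok <- stats$mean > 0 & stats$cv2 > 0
  if (!all(ok)) {
    warn(sprintf("%d gene(s) with non-positive mean or CV^2 dropped from DM",
                 sum(!ok)))
    stats <- stats[ok, ]
  }
  if (nrow(stats) < window_genes) {
    abort("fewer genes than the running-median window")
  }
  o1 <- order(log10(stats$mean), stats$gene_id)
  lcv2 <- log10(stats$cv2)
  r <- numeric(nrow(stats))
  r[o1] <- lcv2[o1] - running_median(lcv2[o1], window_genes)
  o2 <- order(log10(stats$length), stats$gene_id)
  dm <- numeric(nrow(stats))
  dm[o2] <- r[o2] - running_median(r[o2], window_genes)
  stats$dm <- dm
  stats
}

#' Bimodality index of an expression profile
#'
#' Fits an equal-variance two-component Gaussian mixture to
#' `log2(normalized count + 1)` (via mclust, model "E") and scores bimodality
#' as `BI = sqrt(p (1 - p)) * (mu_high - mu_low) / sigma`, where `p` is the
#' mixing proportion of the high component. `pi_he` is the proportion of
#' cells assigned to the high-expression (HE) component by expected
#' membership; `pi_le = 1 - pi_he`.
#'
#' @param x numeric vector of normalized counts for one gene across cells.
#' @param min_cells minimum number of cells (default 10).
#' @return A one-row tibble: `mu_low`, `mu_high`, `sigma`, `p`,
#'   `bimodality_index`, `pi_he`, `converged`. On failure the fit columns are
#'   `NA` and `converged` is `FALSE`.
#' @export
bimodality_index <- function(x, min_cells = 10) {
  if (length(x) < min_cells) abort("too few cells for a mixture fit")
  y <- log2(x + 1)
  na_row <- tibble(mu_low = NA_real_, mu_high = NA_real_, sigma = NA_real_,
                   p = NA_real_, bimodality_index = NA_real_,
                   pi_he = NA_real_, converged = FALSE)
  if (sd(y) == 0) {
    # a constant profile is the degenerate one-component case: BI = 0
    return(tibble(mu_low = y[1], mu_high = y[1], sigma = 0, p = 0,
                  bimodality_index = 0, pi_he = 0, converged = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(Mclust(y, G = 2, modelNames = "E", verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(na_row)
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq[1])
  pro <- fit$parameters$pro
  hi <- which.max(mu)
  p <- pro[hi]
  bi <- sqrt(p * (1 - p)) * abs(diff(range(mu))) / sig
  tibble(mu_low = min(mu), mu_high = max(mu), sigma = sig, p = p,
         bimodality_index = bi, pi_he = p, converged = TRUE)
}

#' Per-gene noise profile
#'
#' Convenience wrapper chaining [compute_cv2()], [compute_dm()] and (when
#' `bimodality = TRUE`) [bimodality_index()] for every gene.
#'
#' @param counts normalized [count_matrix()].
#' @param annotation annotation tibble with `gene_id` and `length`.
#' @param window_genes running-median window for DM.
#' @param bimodality fit the mixture per gene (slower).
#' @return A tibble of class `noise_profile`: `gene_id`, `mean`, `cv2`,
#'   `length`, `dm` and, when requested, `bimodality_index`, `pi_he`.
#' @export
noise_profile <- function(counts, annotation, window_genes = 50,
                          bimodality = FALSE) {
  out <- compute_cv2(counts) |> compute_dm(annotation, window_genes)
  if (bimodality) {
    m <- counts$normalized %||% counts$counts
    fits <- map(out$gene_id, ~ bimodality_index(m[, .x]))
    out$bimodality_index <- map_dbl(fits, "bimodality_index")
    out$pi_he <- map_dbl(fits, "pi_he")
  }
  class(out) <- c("noise_profile", class(out))
  out
}

#' Expression-matched control set
#'
#' Greedy nearest-mean matching without replacement: genes of `set_a` are
#' visited in random-free deterministic order (sorted by mean, ties by id)
#' and each is paired with the as-yet-unmatched `set_b` gene with the closest
#' mean expression. Used to compare classes free of expression-level
#' confounding.
#'
#' @param stats tibble with `gene_id` and `mean`.
#' @param set_a,set_b character vectors of gene ids.
#' @return A tibble of pairs: `gene_a`, `gene_b`, `mean_a`, `mean_b`. When
#'   `set_b` is smaller than `set_a` a partial matching is returned with a
#'   warning.
#' @export
match_expression <- function(stats, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) abort("both sets must be nonempty")
  mu <- setNames(stats$mean, stats$gene_id)
  if (!all(set_a %in% names(mu)) || !all(set_b %in% names(mu))) {
    abort("all genes in both sets must appear in `stats`")
  }
  if (length(set_b) < length(set_a)) {
    warn("set_b smaller than set_a: partial matching")
  }
  a <- set_a[order(mu[set_a], set_a)]
  b <- set_b[order(mu[set_b], set_b)]
  used <- rep(FALSE, length(b))
  pairs <- vector("list", min(length(a), length(b)))
  k <- 0
  for (g in a) {
    if (all(used)) break
    idx <- which(!used)
    j <- idx[which.min(abs(mu[b[idx]] - mu[g]))]
    used[j] <- TRUE
    k <- k + 1
    pairs[[k]] <- tibble(gene_a = g, gene_b = b[j],
                         mean_a = unname(mu[g]), mean_b = unname(mu[b[j]]))
  }
  bind_rows(pairs[seq_len(k)])
}
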