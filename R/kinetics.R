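# Poisson-beta stationary model of transcriptional bursting
#
# A two-state promoter switching on at rate k_on and off at rate k_off
# (in units of the mRNA decay rate) and transcribing at rate s while on has
# stationary mRNA counts distributed as Poisson(s * p) with
# p ~ Beta(k_on, k_off). Burst size = s / k_off, burst frequency = k_on.

# run code under a local RNG state; NULL seed leaves the global stream alone
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate stationary Poisson-beta mRNA counts
#'
#' Each cell draws an active fraction `p ~ Beta(k_on, k_off)` and a count
#' `~ Poisson(s * p)`. Parameters are in units of the mRNA decay rate.
#'
#' @param k_on,k_off,s positive kinetic parameters.
#' @param n_cells number of cells to draw.
#' @param seed optional seed for reproducibility (the global RNG state is
#'   restored afterwards).
#' @return Integer vector of length `n_cells`.
#' @export
pb_simulate <- function(k_on, k_off, s, n_cells, seed = NULL) {
  stopifnot(k_on > 0, k_off > 0, s > 0, n_cells >= 1)
  local_seed(seed, {
    p <- rbeta(n_cells, k_on, k_off)
    rpois(n_cells, s * p)
  })
}

# closed-form moment estimator from the first three factorial moments.
# With r1 = f1, r2 = f2/f1, r3 = f3/f2 (f_k the k-th factorial moment),
#   r1 = s a/(a+b), r2 = s (a+1)/(a+b+1), r3 = s (a+2)/(a+b+2)
# and the system inverts to the expressions below.
pb_moment_solve <- function(x) {
  f1 <- mean(x)
  f2 <- mean(x * (x - 1))
  f3 <- mean(x * (x - 1) * (x - 2))
  if (f1 <= 0 || f2 <= 0 || f3 <= 0) {
    return(list(k_on = NA_real_, k_off = NA_real_, s = NA_real_, ok = FALSE))
  }
  r1 <- f1; r2 <- f2 / f1; r3 <- f3 / f2
  den_a <- r1 * r2 - 2 * r1 * r3 + r2 * r3
  den_s <- r1 - 2 * r2 + r3
  k_on <- 2 * r1 * (r3 - r2) / den_a
  k_off <- 2 * (r1 - r2) * (r1 - r3) * (r2 - r3) / (den_s * den_a)
  s <- (2 * r1 * r3 - r1 * r2 - r2 * r3) / den_s
  # near-Poisson data (all moment ratios equal) makes the system singular and
  # k_on blow up: such fits are flagged rather than reported
  ok <- all(is.finite(c(k_on, k_off, s))) && k_on > 0 && k_off > 0 && s > 0 &&
    k_on < 1e3
  list(k_on = k_on, k_off = k_off, s = s, ok = ok)
}

#' Fit Poisson-beta burst kinetics to one gene
#'
#' Reference estimator: the first three theoretical factorial moments of the
#' Poisson-beta stationary distribution are matched to their sample
#' counterparts and solved in closed form for `(k_on, k_off, s)`. Fitted
#' parameters are expressed per unit time by rescaling with the supplied
#' mRNA decay rate `d` (default 1, i.e. per mRNA lifetime); the burst size
#' `s / k_off` is invariant under this rescaling.
#'
#' @param x vector of counts across cells (normalized counts are rounded to
#'   the nearest integer when `round = TRUE`).
#' @param decay per-gene mRNA decay rate `d` (> 0).
#' @param min_cells minimum number of cells required (default 30).
#' @param round round `x` to integers before fitting.
#' @return An object of class `pb_fit` with elements `k_on`, `k_off`, `s`
#'   (per unit time), `burst_size`, `burst_freq`, `decay`, `n`, `moment_ok`,
#'   `identifiable` (provisional: moment solution positive and finite; see
#'   [pb_identifiability()] for the bootstrap test) and `gof_p` (`NA` until
#'   tested). A gene whose moment system has no positive solution (e.g. data
#'   indistinguishable from pure Poisson) is returned flagged, not errored.
#' @export
pb_fit <- function(x, decay = 1, min_cells = 30, round = TRUE) {
  if (length(x) < min_cells) abort("too few cells for a kinetic fit")
  if (decay <= 0) abort("decay rate must be positive")
  if (round) x <- round(x)
  if (all(x == x[1])) {
    abort("degenerate input: constant (or all-zero) count vector",
          class = "burstnoise_degenerate_input")
  }
  sol <- pb_moment_solve(x)
  fit <- structure(
    list(
      k_on = sol$k_on * decay, k_off = sol$k_off * decay, s = sol$s * decay,
      burst_size = if (sol$ok) sol$s / sol$k_off else NA_real_,
      burst_freq = sol$k_on * decay,
      decay = decay, n = length(x), moment_ok = sol$ok,
      identifiable = sol$ok, gof_p = NA_real_
    ),
    class = "pb_fit"
  )
  fit
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf(
    "<pb_fit> k_on=%.3g k_off=%.3g s=%.3g (burst size %.3g, freq %.3g) n=%d%s\n",
    x$k_on, x$k_off, x$s, x$burst_size, x$burst_freq, x$n,
    if (!x$moment_ok) " [non-identifiable]"
    else if (!is.na(x$gof_p)) sprintf(" gof_p=%.3f", x$gof_p) else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pb_fit <- function(x, ...) {
  tibble(
    term = c("k_on", "k_off", "s", "burst_size", "burst_freq"),
    estimate = c(x$k_on, x$k_off, x$s, x$burst_size, x$burst_freq)
  )
}

#' @exportS3Method generics::glance
glance.pb_fit <- function(x, ...) {
  tibble(n = x$n, decay = x$decay, moment_ok = x$moment_ok,
         gof_p = x$gof_p, identifiable = x$identifiable)
}

# bin probabilities of the fitted Poisson-beta law (unit-decay scale) on
# count bins [lo, hi]; hi = Inf allowed. Gauss-Legendre on the Beta quantile
# scale avoids the density's endpoint singularities.
# pmf of the fitted law for k = 0..kmax, integrated on the Beta quantile
# scale (Gauss-Legendre), which avoids the density's endpoint singularities
pb_pmf <- function(kmax, k_on, k_off, s, gl) {
  lam <- s * qbeta(gl$x, k_on, k_off)
  as.numeric(outer(0:kmax, lam, dpois) %*% gl$w)
}

# chi-square statistic on adaptive count bins (expected >= min_expected per
# bin under the fitted law; open tail bin)
pb_gof_stat <- function(x, k_on, k_off, s, gl, min_expected = 5) {
  n <- length(x)
  kmax <- max(x)
  pk <- pb_pmf(kmax, k_on, k_off, s, gl)
  csum <- cumsum(pk)
  # greedy upper bin edges: close a bin once its expected count reaches target
  ub <- integer(0); prev <- 0
  for (k in 0:kmax) {
    if (n * (csum[k + 1] - prev) >= min_expected) {
      ub <- c(ub, k); prev <- csum[k + 1]
    }
  }
  pbin <- diff(c(0, csum[ub + 1]))
  ptail <- 1 - sum(pbin)
  if (length(ub) > 0 && n * ptail < min_expected) {
    ptail <- ptail + pbin[length(pbin)]
    pbin <- pbin[-length(pbin)]
    ub <- ub[-length(ub)]
  }
  probs <- c(pbin, ptail)
  obs <- tabulate(findInterval(x, c(-0.5, ub + 0.5)), nbins = length(probs))
  e <- n * probs
  sum((obs - e)^2 / pmax(e, .Machine$double.eps))
}

#' Parametric-bootstrap identifiability / goodness-of-fit test
#'
#' The statistic is a chi-square distance between the observed counts and the
#' fitted Poisson-beta law on adaptive count bins (expected count at least 5
#' per bin). `n_boot` datasets are simulated from the fit; each is refitted
#' and its statistic computed against its own refit, so parameter estimation
#' is accounted for. `gof_p` is the fraction of bootstrap statistics at least
#' as large as the observed one; the fit is declared identifiable when
#' `gof_p >= alpha` and the moment solution is finite and positive.
#'
#' @param x the counts the fit was computed from (rounded if needed).
#' @param fit a [pb_fit()] object.
#' @param n_boot bootstrap replicates (default 200).
#' @param alpha rejection level (default 0.05).
#' @param seed optional seed.
#' @return The `pb_fit` with `gof_p` and `identifiable` filled in.
#' @export
pb_identifiability <- function(x, fit, n_boot = 200, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(fit, "pb_fit"))
  x <- round(x)
  if (!fit$moment_ok) {
    fit$gof_p <- NA_real_
    fit$identifiable <- FALSE
    return(fit)
  }
  # work on the unit-decay scale: the stationary law is decay-invariant
  a <- fit$k_on / fit$decay; b <- fit$k_off / fit$decay; s <- fit$s / fit$decay
  gl <- pracma::gaussLegendre(64, 0, 1)
  t_obs <- pb_gof_stat(x, a, b, s, gl)
  n <- length(x)
  t_boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      xb <- rpois(n, s * rbeta(n, a, b))
      solb <- pb_moment_solve(xb)
      if (!solb$ok) return(NA_real_)
      pb_gof_stat(xb, solb$k_on, solb$k_off, solb$s, gl)
    }, numeric(1))
  })
  ok <- !is.na(t_boot)
  if (sum(ok) < n_boot) {
    warn(sprintf("%d of %d bootstrap refits failed; p from completed replicates",
                 n_boot - sum(ok), n_boot))
  }
  fit$gof_p <- mean(t_boot[ok] >= t_obs)
  fit$identifiable <- fit$moment_ok && fit$gof_p >= alpha
  fit
}

#' Fit burst kinetics for every gene of a count matrix
#'
#' @param counts normalized [count_matrix()] (normalized counts are rounded
#'   to integers before fitting; raw counts are used when no normalization is
#'   present).
#' @param decay optional decay table (`gene_id`, `decay`); genes absent from
#'   it use `d = 1`.
#' @param min_cells minimum cells per gene.
#' @param n_boot bootstrap replicates for the identifiability test; 0 skips
#'   the test (all `gof_p` are `NA`, `identifiable` reflects the moment
#'   solution only).
#' @param alpha rejection level for the identifiability test.
#' @param seed seed for the bootstrap.
#' @return A tibble of class `kinetic_fits`: `gene_id`, `k_on`, `k_off`,
#'   `s`, `burst_size`, `burst_freq`, `decay`, `gof_p`, `identifiable`.
#' @export
fit_kinetics <- function(counts, decay = NULL, min_cells = 30, n_boot = 0,
                         alpha = 0.05, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$normalized %||% counts$counts
  d <- setNames(rep(1, length(counts$genes)), counts$genes)
  if (!is.null(decay)) d[decay$gene_id[decay$gene_id %in% names(d)]] <-
    decay$decay[decay$gene_id %in% names(d)]
  seeds <- if (is.null(seed)) rep(list(NULL), length(counts$genes))
           else as.list(local_seed(seed, sample.int(.Machine$integer.max,
                                                    length(counts$genes))))
  rows <- map(seq_along(counts$genes), function(i) {
    g <- counts$genes[i]
    x <- round(m[, g])
    fit <- tryCatch(pb_fit(x, decay = d[[g]], min_cells = min_cells,
                           round = FALSE),
                    burstnoise_degenerate_input = function(e) NULL,
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(gene_id = g, k_on = NA_real_, k_off = NA_real_,
                    s = NA_real_, burst_size = NA_real_, burst_freq = NA_real_,
                    decay = d[[g]], gof_p = NA_real_, identifiable = FALSE))
    }
    if (n_boot > 0 && fit$moment_ok) {
      fit <- pb_identifiability(x, fit, n_boot = n_boot, alpha = alpha,
                                seed = seeds[[i]])
    }
    tibble(gene_id = g, k_on = fit$k_on, k_off = fit$k_off, s = fit$s,
           burst_size = fit$burst_size, burst_freq = fit$burst_freq,
           decay = d[[g]], gof_p = fit$gof_p, identifiable = fit$identifiable)
  })
  out <- bind_rows(rows)
  class(out) <- c("kinetic_fits", class(out))
  out
}
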