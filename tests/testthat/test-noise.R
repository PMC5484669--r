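test_that("CV^2 matches closed forms: constant, Poisson, negative binomial", {
  set.seed(21)
  n <- 2000
  m <- cbind(
    const = rep(7L, n),
    pois = rpois(n, 50),
    nb = rnbinom(n, size = 2, mu = 20)
  )
  cm <- toy_counts(m, genes = colnames(m))
  cm$normalized <- cm$counts
  st <- compute_cv2(cm)
  expect_equal(st$cv2[st$gene_id == "const"], 0)
  # Poisson: cv2 -> 1/lambda
  expect_equal(st$cv2[st$gene_id == "pois"], 1 / 50, tolerance = 0.1)
  # NB: cv2 -> 1/mu + 1/size (analytic moments)
  expect_equal(st$cv2[st$gene_id == "nb"], 1 / 20 + 1 / 2, tolerance = 0.1)
})

test_that("zero-mean genes are excluded from CV^2 with a warning", {
  m <- cbind(a = rpois(50, 5), b = rep(0L, 50))
  cm <- toy_counts(m, genes = colnames(m))
  expect_warning(st <- compute_cv2(cm), "zero-mean")
  expect_equal(st$gene_id, "a")
})

make_noise_table <- function(n, noise_sd = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    mean = rlnorm(n, log(50), 1),
    length = round(rlnorm(n, log(2e4), 0.8)),
    cv2 = 10^(-0.8 * log10(rlnorm(n, log(50), 1)) + rnorm(n, 0, noise_sd))
  )
}

test_that("DM ranks the noisier of two otherwise identical genes higher", {
  tab <- make_noise_table(200, noise_sd = 0.1)
  tab$cv2 <- 10^(-0.8 * log10(tab$mean))  # deterministic baseline
  # plant a matched pair: same mean and length, double CV^2
  tab$mean[1] <- tab$mean[2] <- 30
  tab$length[1] <- tab$length[2] <- 20000
  tab$cv2[1] <- 10^(-0.8 * log10(30))
  tab$cv2[2] <- 2 * tab$cv2[1]
  dm <- compute_dm(tab)
  expect_gt(dm$dm[dm$gene_id == "g0002"], dm$dm[dm$gene_id == "g0001"])
})

test_that("DM is ~0 on a null where CV^2 is a deterministic function of mean", {
  n <- 1000
  set.seed(5)
  tab <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    mean = rlnorm(n, log(50), 1),
    length = round(rlnorm(n, log(2e4), 0.8)),
  )
  tab$cv2 <- 10^(-0.9 * log10(tab$mean) + 0.3)
  dm <- compute_dm(tab)
  # interior genes (away from both sort edges) have dm == 0 by construction
  interior <- dm[rank(dm$mean) > 50 & rank(dm$mean) < n - 50 &
                   rank(dm$length) > 50 & rank(dm$length) < n - 50, ]
  expect_lt(max(abs(interior$dm)), 1e-10)
})

test_that("DM is location-free: a global CV^2 scaling leaves it unchanged", {
  tab <- make_noise_table(500, noise_sd = 0.3, seed = 9)
  dm1 <- compute_dm(tab)
  tab2 <- tab
  tab2$cv2 <- tab2$cv2 * 10^0.7
  dm2 <- compute_dm(tab2)
  expect_equal(dm1$dm, dm2$dm, tolerance = 1e-12)
})

test_that("running-median window larger than the gene count errors", {
  tab <- make_noise_table(30)
  expect_error(compute_dm(tab, window_genes = 50), "fewer genes")
})

test_that("bimodality index: degenerate and planted-mixture oracles", {
  set.seed(31)
  # single Gaussian: estimated separation shrinks, BI near 0
  y <- rnorm(5000, 4, 1)
  bi1 <- bimodality_index(2^y - 1)
  expect_lt(bi1$bimodality_index, 0.6)
  # 50/50 mixture, separation 3 sigma: BI = sqrt(0.25) * 3 = 1.5
  y2 <- c(rnorm(5000, 2, 1), rnorm(5000, 5, 1))
  bi2 <- bimodality_index(2^y2 - 1)
  expect_equal(bi2$bimodality_index, 1.5, tolerance = 0.05)
  expect_equal(bi2$pi_he, 0.5, tolerance = 0.05)
  # constant profile: BI = 0 by convention
  expect_equal(bimodality_index(rep(3, 100))$bimodality_index, 0)
})

test_that("bimodality index is invariant to affine transforms of the log scale", {
  set.seed(32)
  y <- c(rnorm(500, 2, 1), rnorm(1500, 6, 1))
  bi_a <- bimodality_index(2^y - 1)
  bi_b <- bimodality_index(2^(1.7 * y + 3) - 1)
  expect_equal(bi_a$bimodality_index, bi_b$bimodality_index, tolerance = 0.05)
})

test_that("expression matching pairs nearest means without replacement", {
  stats <- tibble::tibble(
    gene_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    mean = c(1, 5, 9, 1.1, 5.2, 20)
  )
  pairs <- match_expression(stats, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  # oracle: exhaustive search over the 6 assignments minimizes total distance
  # at (1<->1.1)(5<->5.2)(9<->20)
  expect_equal(pairs$gene_b[match(c("a1", "a2", "a3"), pairs$gene_a)],
               c("b1", "b2", "b3"))

  # identical mean vectors: zero total matching distance
  st2 <- tibble::tibble(gene_id = c("x1", "x2", "y1", "y2"),
                        mean = c(3, 8, 3, 8))
  p2 <- match_expression(st2, c("x1", "x2"), c("y1", "y2"))
  expect_equal(sum(abs(p2$mean_a - p2$mean_b)), 0)

  # one-element sets give the single cross pair
  p3 <- match_expression(st2, "x1", "y2")
  expect_equal(nrow(p3), 1)
  expect_equal(p3$gene_b, "y2")

  # smaller set_b: partial matching with a warning
  expect_warning(p4 <- match_expression(stats, c("a1", "a2", "a3"),
                                        c("b1", "b2")), "partial")
  expect_equal(nrow(p4), 2)
})
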