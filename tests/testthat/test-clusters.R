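# 4-gene window score: (d1+d2)/2 + (d2+d3)/2 + (d3+d4)/2
test_that("window score equals the rolling-pair-mean oracle on small cases", {
  dm <- c(1, 2, 3, 4)
  expect_equal(burstnoise:::window_score(dm), 1.5 + 2.5 + 3.5)
  expect_equal(burstnoise:::window_score(c(-1, 1)), 0)
})

test_that("cluster caller recovers planted noisy runs and stays quiet on constant DM", {
  g <- planted_dm_genome(seed = 2)
  cl <- call_noise_clusters(g$tab, g$ann, n_null = 2e4, seed = 3)
  noisy_members <- unique(unlist(cl$genes[cl$label == "noisy"]))
  recovered <- sum(vapply(g$runs, function(r) mean(r %in% noisy_members) >= 0.5,
                          logical(1)))
  expect_gte(recovered, 9)

  # constant DM: every score ties the null; strict inequality calls nothing
  flat <- g$tab
  flat$dm <- 1
  cl0 <- call_noise_clusters(flat, g$ann, n_null = 5000, seed = 4)
  expect_equal(nrow(cl0), 0)
})

test_that("cluster membership equals the union of its significant windows", {
  g <- planted_dm_genome(seed = 6)
  cl <- call_noise_clusters(g$tab, g$ann, n_null = 2e4, seed = 7)
  wins <- attr(cl, "windows")
  sig <- wins[!is.na(wins$label), ]
  for (lab in unique(cl$label)) {
    expect_setequal(unique(unlist(cl$genes[cl$label == lab])),
                    unique(unlist(sig$genes[sig$label == lab])))
  }
  expect_equal(cl$n_genes, lengths(cl$genes))
})

test_that("windows wider than the span cap are ignored", {
  ann <- toy_annotation(8, spacing = 1e6)  # 1 Mb gaps > 0.5 Mb cap
  tab <- tibble::tibble(gene_id = ann$gene_id, dm = rnorm(8))
  cl <- call_noise_clusters(tab, ann, n_null = 1000, seed = 1)
  expect_equal(nrow(attr(cl, "windows")), 0)
})

test_that("cluster calling is reproducible under a fixed seed", {
  g <- planted_dm_genome(seed = 8, n = 300, n_runs = 4)
  a <- call_noise_clusters(g$tab, g$ann, n_null = 5000, seed = 99)
  b <- call_noise_clusters(g$tab, g$ann, n_null = 5000, seed = 99)
  expect_identical(a$genes, b$genes)
  expect_identical(attr(a, "null_quantiles"), attr(b, "null_quantiles"))
})

test_that("mark enrichment matches the hypergeometric oracle and degenerate rules", {
  g <- planted_dm_genome(seed = 10)
  cl <- call_noise_clusters(g$tab, g$ann, n_null = 2e4, seed = 11)
  # constructed 2x2 (20,80,10,90): compare against exhaustive two-sided sum
  marks <- tibble::tibble(gene_id = sprintf("m%03d", 1:200),
                          mk = rep(c(TRUE, FALSE, TRUE, FALSE),
                                   times = c(20, 80, 10, 90)))
  fake_clusters <- tibble::tibble(
    chromosome = "chr1", start = 1, end = 2, label = "noisy",
    n_genes = 100, genes = list(marks$gene_id[1:100])
  )
  # (no stable cluster in the fixture: its empty-margin warning is expected)
  res <- suppressWarnings(cluster_mark_enrichment(fake_clusters, marks))
  res <- res[res$label == "noisy", ]
  # brute-force two-sided Fisher p: sum of table probabilities <= observed's
  probs <- dhyper(0:30, 30, 170, 100)
  p_oracle <- sum(probs[probs <= dhyper(20, 30, 170, 100) * (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-9)

  # identical in/out proportions: OR = 1, p = 1
  marks2 <- tibble::tibble(gene_id = marks$gene_id,
                           mk = rep(c(TRUE, FALSE), 100))
  res2 <- suppressWarnings(cluster_mark_enrichment(fake_clusters, marks2))
  expect_equal(res2$p[res2$label == "noisy"], 1)

  # empty margin: warning and p = 1
  marks3 <- tibble::tibble(gene_id = marks$gene_id, mk = FALSE)
  w <- testthat::capture_warnings(
    res3 <- cluster_mark_enrichment(fake_clusters, marks3))
  expect_match(w, "empty margin", all = TRUE)
  expect_equal(res3$p[res3$label == "noisy"], 1)
})

test_that("neighborhood noise test separates planted structure from a shuffled null", {
  g <- planted_dm_genome(n = 800, n_runs = 14, run_len = 5, shift = 2, seed = 12)
  res <- neighborhood_noise_test(g$tab, g$ann, window_bp = 2e5,
                                 n_random_genomes = 50, seed = 13)
  expect_lt(res$p_noise, res$rand_lo)

  # exchangeable DM: observed p falls inside the random band
  set.seed(14)
  null_tab <- g$tab
  null_tab$dm <- sample(null_tab$dm)
  res0 <- neighborhood_noise_test(null_tab, g$ann, window_bp = 2e5,
                                  n_random_genomes = 50, seed = 15)
  expect_gte(res0$p_noise, res0$rand_lo)
  expect_lte(res0$p_noise, res0$rand_hi)
})

test_that("flanking-variability trend: planted boost rises, shuffled is flat", {
  set.seed(16)
  n <- 600
  ann <- toy_annotation(n, spacing = 5e4, chroms = paste0("chr", 1:2))
  noisy <- sample(ann$gene_id, 150)
  nbr <- burstnoise:::neighbor_index(
    dplyr::arrange(ann, chromosome, tss, gene_id), 5e4)
  pos <- dplyr::arrange(ann, chromosome, tss, gene_id)
  cnt <- vapply(seq_len(n), function(i) sum(pos$gene_id[nbr[[i]]] %in% noisy),
                numeric(1))
  dm <- rnorm(n, 0, 0.2) + 0.5 * cnt
  tab <- tibble::tibble(gene_id = pos$gene_id, dm = dm)
  active <- setdiff(ann$gene_id, noisy)
  tr <- flanking_variability_trend(tab, ann, active, noisy, window_bp = 5e4)
  expect_gt(tr$trend_rho, 0)
  expect_lt(tr$trend_p, 0.05)

  # shuffled DM: no trend
  tab2 <- tab
  tab2$dm <- sample(tab2$dm)
  tr2 <- flanking_variability_trend(tab2, ann, active, noisy, window_bp = 5e4)
  expect_gt(tr2$trend_p, 0.01)

  # degenerate: all flanker counts equal -> test skipped
  tr3 <- flanking_variability_trend(tab, toy_annotation(60, spacing = 1e7),
                                    pos$gene_id[1:60], character(0),
                                    window_bp = 5e4)
  expect_true(is.na(tr3$trend_p))
})
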