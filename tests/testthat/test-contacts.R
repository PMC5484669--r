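test_that("long-range filter drops close intrachromosomal pairs only, idempotently", {
  ints <- toy_interactions(
    chr_a = c("chr1", "chr1", "chr2", "chr1", "chr3", "chr1"),
    pos_a = c(1e6, 1e6, 5e6, 2e6, 1e6, 1e6),
    chr_b = c("chr1", "chr2", "chr2", "chr1", "chr3", "chr1"),
    pos_b = c(6e6, 9e9, 30e6, 2.5e6, 50e6, 20e6)
  )
  out <- filter_long_range(ints)
  # oracle by direct check: rows 1 (5 Mb) and 4 (0.5 Mb) are removed
  expect_equal(nrow(out), 4)
  expect_true(all(abs((out$start_a + out$end_a) / 2 -
                        (out$start_b + out$end_b) / 2) >= 1e7 |
                    out$chr_a != out$chr_b))
  expect_identical(filter_long_range(out), out)
})

test_that("contact enrichment ~3 for a 3x planted set and ~1 for a null set", {
  pc <- planted_contacts(boost = 3, seed = 31)
  enr <- contact_enrichment(pc$ints, pc$set, pc$ann, n_sets = 30,
                            n_groups = 3, seed = 32)
  expect_equal(enr$enrichment, 3, tolerance = 0.15)
  expect_true(all(enr$per_set$ks_distance < 0.2, na.rm = TRUE))

  # a random same-size set is its own control: enrichment within 1 +- 2 sd
  set.seed(33)
  null_set <- sample(pc$ann$gene_id, length(pc$set))
  enr0 <- contact_enrichment(pc$ints, null_set, pc$ann, n_sets = 30,
                             n_groups = 3, seed = 34)
  spread <- sd(enr0$observed / pmax(enr0$per_set$count, 1))
  expect_lt(abs(enr0$enrichment - 1), 2 * max(spread, 0.05))
})

test_that("enrichment comparison detects the planted ordering", {
  pc <- planted_contacts(boost = 3, seed = 35)
  enr_hi <- contact_enrichment(pc$ints, pc$set, pc$ann, n_sets = 20,
                               n_groups = 3, seed = 36)
  set.seed(37)
  null_set <- sample(setdiff(pc$ann$gene_id, pc$set), 150)
  enr_lo <- contact_enrichment(pc$ints, null_set, pc$ann, n_sets = 20,
                               n_groups = 3, seed = 38)
  cmp <- compare_contact_enrichment(enr_hi, enr_lo, alternative = "greater")
  expect_lt(cmp$p, 0.01)
})

test_that("promoter-class preference finds planted assortativity and not its absence", {
  set.seed(41)
  n <- 300
  ann <- toy_annotation(n, spacing = 2e6, chroms = paste0("chr", 1:3))
  states <- tibble::tibble(
    gene_id = ann$gene_id,
    state = sample(c("Active", "PRCa", "PRCr"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  )
  cls <- setNames(states$state, states$gene_id)
  ia <- sample(n, 20000, replace = TRUE)
  ib <- sample(n, 20000, replace = TRUE)
  ok <- ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  same <- cls[ann$gene_id[ia]] == cls[ann$gene_id[ib]]
  keep <- runif(length(ia)) < ifelse(same, 1, 0.2)  # 5x within-class odds
  ints <- toy_interactions(
    chr_a = ann$chromosome[ia[keep]], pos_a = ann$tss[ia[keep]],
    chr_b = ann$chromosome[ib[keep]], pos_b = ann$tss[ib[keep]],
    genes_a = as.list(ann$gene_id[ia[keep]]),
    genes_b = as.list(ann$gene_id[ib[keep]])
  )
  pref <- promoter_class_preference(ints, states)
  expect_true(all(pref$preference$odds_ratio > 1))
  expect_true(all(pref$preference$p < 0.01))

  # uniform partner classes: odds ratios near 1
  ints0 <- toy_interactions(
    chr_a = ann$chromosome[ia], pos_a = ann$tss[ia],
    chr_b = ann$chromosome[ib], pos_b = ann$tss[ib],
    genes_a = as.list(ann$gene_id[ia]), genes_b = as.list(ann$gene_id[ib])
  )
  pref0 <- promoter_class_preference(ints0, states)
  expect_true(all(abs(log(pref0$preference$odds_ratio)) < 0.25))

  # single-contact input: tests are skipped, table has one cell
  one <- ints[1, ]
  class(one) <- class(ints)
  pref1 <- promoter_class_preference(one, states)
  expect_equal(sum(pref1$pair_counts$n), 1)
  expect_true(all(is.na(pref1$preference$p)))
})

test_that("enhancer link summary counts per class with zeros for unlinked genes", {
  ann <- toy_annotation(4, spacing = 1e6)
  ints <- toy_interactions(
    chr_a = rep("chr1", 3), pos_a = c(1e5, 1e5, 2e5),
    chr_b = rep("chr1", 3), pos_b = c(5e6, 6e6, 7e6),
    a_kind = "promoter", b_kind = "enhancer",
    enhancer_class = c("active", "poised", "active"),
    genes_a = list("g001", "g001", "g002")
  )
  out <- enhancer_link_summary(ints, ann$gene_id)
  expect_equal(out$n_active[out$gene_id == "g001"], 1)
  expect_equal(out$n_poised[out$gene_id == "g001"], 1)
  expect_equal(out$n_active[out$gene_id == "g002"], 1)
  expect_equal(sum(out$n_active) + sum(out$n_poised) + sum(out$n_intermediate), 3)
  expect_equal(out$n_active[out$gene_id == "g004"], 0)
})

test_that("enhancer-noise association: planted stabilization found, shuffled null quiet", {
  set.seed(51)
  n_prca <- 200
  links <- tibble::tibble(
    gene_id = sprintf("p%03d", 1:n_prca),
    n_active = rpois(n_prca, 1.5),
    n_intermediate = 0L,
    n_poised = 0L
  )
  prcr_links <- tibble::tibble(gene_id = sprintf("r%03d", 1:100),
                               n_active = rpois(100, 0.2),
                               n_intermediate = 0L, n_poised = rpois(100, 1))
  all_links <- dplyr::bind_rows(links, prcr_links)
  states <- tibble::tibble(
    gene_id = all_links$gene_id,
    state = rep(c("PRCa", "PRCr"), c(n_prca, 100))
  )
  # DM decreases with planted active-enhancer count; mean expression unrelated
  noise <- tibble::tibble(
    gene_id = all_links$gene_id,
    dm = rnorm(300, 0, 0.15) - 0.3 * all_links$n_active,
    mean = rlnorm(300, log(40), 0.3)
  )
  res <- enhancer_noise_association(all_links, noise, states)
  expect_lt(res$class_tests$p[1], 1e-6)     # PRCa >> PRCr active contacts
  expect_lt(res$class_tests$p[2], 1e-6)     # poised the other way
  expect_lt(res$noise_test$p_dm, 0.05)
  expect_gt(res$noise_test$median_dm_low, res$noise_test$median_dm_high)
  expect_gt(res$noise_test$p_mean_control, 0.01)

  # shuffled enhancer counts: association gone
  shuf <- all_links
  set.seed(52)
  shuf$n_active <- sample(shuf$n_active)
  res0 <- enhancer_noise_association(shuf, noise, states)
  expect_gt(res0$noise_test$p_dm, 0.01)
})
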