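# Synthetic-data generator with known ground truth for every pipeline stage.

#' Simulation configuration
#'
#' Defaults describe a desk-scale mESC-like experiment: 90 cells, four
#' promoter classes with distinct burst kinetics (Active: frequent bursts;
#' PRCa: infrequent bursts giving bimodal profiles; PRCr: mostly off with
#' rare large bursts; other: broad), log-normal cell size factors, a
#' multi-chromosome layout with PRCa genes placed preferentially next to
#' PRCr genes, planted noisy clusters, a class-assortative promoter contact
#' network, enhancer links whose count raises PRCa burst frequency (at
#' constant mean), and a paired knockout condition multiplying the burst
#' frequency of PRC targets. Kinetic hyper-parameters are `(meanlog, sdlog)`
#' of log-normal draws, in units of the mRNA decay rate.
#'
#' @param n_cells cells per condition.
#' @param genes_per_class named integer vector over
#'   `Active`, `PRCa`, `PRCr`, `other`.
#' @param kinetics per-class list of `k_on`, `k_off`, `s` hyper-parameters.
#' @param size_factor_sdlog log-normal sdlog of per-cell size factors.
#' @param n_chromosomes chromosomes in the synthetic genome.
#' @param spacing_mean mean TSS spacing in bp (exponential gaps).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths.
#' @param n_clusters,cluster_size planted noisy clusters (consecutive genes
#'   whose `k_on` is divided, mean preserved).
#' @param cluster_kon_factor multiplier (< 1) applied to clustered genes'
#'   `k_on`.
#' @param adjacency_strength how strongly PRCa genes follow PRCr genes (and
#'   vice versa) along the chromosome; 0 gives an exchangeable layout.
#' @param n_contacts promoter-promoter contacts drawn.
#' @param contact_assortativity additional within-class odds for contacts
#'   (weight `1 + assortativity` for same-class pairs); 0 gives a class-blind
#'   network.
#' @param enhancer_link_rate mean active-enhancer links per PRCa gene
#'   (Poisson).
#' @param enhancer_kon_effect per-link multiplier on PRCa `k_on`
#'   (`1 + effect * n_links`, mean preserved); 0 disables the effect.
#' @param dko_kon_multiplier `k_on` multiplier for PRC targets (PRCa, PRCr)
#'   in the knockout condition.
#' @param seed master seed; every stochastic step derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 90,
                       genes_per_class = c(Active = 600, PRCa = 300,
                                           PRCr = 200, other = 400),
                       kinetics = list(
                         Active = list(k_on = c(log(4), 0.4),
                                       k_off = c(log(6), 0.4),
                                       s = c(log(120), 0.4)),
                         PRCa = list(k_on = c(log(0.6), 0.4),
                                     k_off = c(log(3), 0.4),
                                     s = c(log(150), 0.4)),
                         PRCr = list(k_on = c(log(0.15), 0.4),
                                     k_off = c(log(4), 0.4),
                                     s = c(log(350), 0.3)),
                         other = list(k_on = c(log(2), 0.6),
                                      k_off = c(log(5), 0.5),
                                      s = c(log(100), 0.6))
                       ),
                       size_factor_sdlog = 0.3,
                       n_chromosomes = 5,
                       spacing_mean = 8e4,
                       gene_length_meanlog = log(2e4),
                       gene_length_sdlog = 0.8,
                       n_clusters = 10, cluster_size = 5,
                       cluster_kon_factor = 0.25,
                       adjacency_strength = 3,
                       n_contacts = 2000,
                       contact_assortativity = 5,
                       enhancer_link_rate = 1.2,
                       enhancer_kon_effect = 0.4,
                       dko_kon_multiplier = 4,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(genes_per_class >= 0), n_cells >= 2,
            cluster_kon_factor > 0, dko_kon_multiplier > 0,
            adjacency_strength >= 0, contact_assortativity >= 0,
            enhancer_kon_effect >= 0)
  structure(cfg, class = "sim_config")
}

# rescale s so the stationary mean s*kon/(kon+koff) is unchanged after
# replacing k_on
preserve_mean_s <- function(s, kon_old, kon_new, koff) {
  s * (kon_old / (kon_old + koff)) / (kon_new / (kon_new + koff))
}

# lay classes along the genome with optional PRCa-next-to-PRCr preference
place_classes <- function(classes_pool, strength) {
  n <- length(classes_pool)
  remaining <- table(classes_pool)
  lvls <- names(remaining)
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    wts <- as.numeric(remaining)
    boost <- (prev == "PRCr" & lvls == "PRCa") |
      (prev == "PRCa" & lvls == "PRCr")
    wts <- wts * (1 + strength * boost)
    pick <- sample(lvls, 1, prob = wts)
    out[i] <- pick
    remaining[pick] <- remaining[pick] - 1
    prev <- pick
  }
  out
}

#' Simulate a full synthetic dataset
#'
#' Produces every input the pipeline consumes — wild-type and knockout count
#' matrices, gene annotation, chromatin-state table, promoter/enhancer
#' interaction list, per-gene enhancer-link counts — together with the ground
#' truth (kinetic parameters per condition, planted clusters, the contact
#' network). Counts are `Poisson(sf_c * s_g * p)` with
#' `p ~ Beta(k_on_g, k_off_g)` per cell. Fully reproducible under the master
#' seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all files are written in
#'   the dialects the readers accept (counts TSV, annotation BED6, states
#'   TSV, interactions TSV, truth tables).
#' @return A list: `wt`, `dko` ([count_matrix()]s), `annotation`, `states`,
#'   `interactions`, `links`, `qc_table`, `truth` (list with `params`,
#'   `clusters`, `contacts`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    gpc <- config$genes_per_class
    n_genes <- sum(gpc)
    if (config$n_clusters * config$cluster_size > n_genes / 2) {
      abort("infeasible layout: too many planted clusters for the gene count")
    }
    # genome layout -----------------------------------------------------
    chrom <- sort(rep_len(paste0("chr", seq_len(config$n_chromosomes)), n_genes))
    gaps <- stats::rexp(n_genes, 1 / config$spacing_mean) + 1000
    tss <- unlist(lapply(split(gaps, chrom), function(g) 1e6 + cumsum(g)),
                  use.names = FALSE)
    tss <- round(tss)
    len <- round(rlnorm(n_genes, config$gene_length_meanlog,
                        config$gene_length_sdlog)) + 200
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    pool_global <- sample(rep(names(gpc), times = gpc))
    classes <- character(n_genes)
    offset <- 0
    for (idx in split(seq_len(n_genes), chrom)) {
      sub <- pool_global[(offset + 1):(offset + length(idx))]
      classes[idx] <- place_classes(sub, config$adjacency_strength)
      offset <- offset + length(idx)
    }
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    annotation <- tibble(
      gene_id = gene_id, chromosome = chrom,
      start = ifelse(strand == "+", tss, pmax(1, tss - len + 1)),
      end = ifelse(strand == "+", tss + len - 1, tss),
      tss = tss, strand = strand, length = len
    )
    states <- tibble(gene_id = gene_id, state = classes)

    # kinetics ----------------------------------------------------------
    draw <- function(h, n) rlnorm(n, h[1], h[2])
    k_on <- k_off <- s <- numeric(n_genes)
    for (cl in names(gpc)) {
      idx <- which(classes == cl)
      h <- config$kinetics[[cl]]
      k_on[idx] <- draw(h$k_on, length(idx))
      k_off[idx] <- draw(h$k_off, length(idx))
      s[idx] <- draw(h$s, length(idx))
    }

    # planted noisy clusters: runs of consecutive genes, lowered k_on,
    # mean preserved
    cluster_id <- rep(NA_integer_, n_genes)
    ord <- order(chrom, tss)
    taken <- rep(FALSE, n_genes)
    placed <- 0
    guard <- 0
    while (placed < config$n_clusters && guard < 10000) {
      guard <- guard + 1
      st <- sample.int(n_genes - config$cluster_size + 1, 1)
      run <- ord[st:(st + config$cluster_size - 1)]
      if (any(taken[run])) next
      if (length(unique(chrom[run])) > 1) next
      placed <- placed + 1
      taken[run] <- TRUE
      cluster_id[run] <- placed
      kon_new <- k_on[run] * config$cluster_kon_factor
      s[run] <- preserve_mean_s(s[run], k_on[run], kon_new, k_off[run])
      k_on[run] <- kon_new
    }
    if (placed < config$n_clusters) {
      abort("infeasible layout: could not place all clusters")
    }

    # enhancer links raise PRCa burst frequency at constant mean ---------
    n_active_link <- integer(n_genes)
    n_poised_link <- integer(n_genes)
    n_inter_link <- integer(n_genes)
    prca <- which(classes == "PRCa")
    prcr <- which(classes == "PRCr")
    act <- which(classes == "Active")
    n_active_link[prca] <- rpois(length(prca), config$enhancer_link_rate)
    n_active_link[act] <- rpois(length(act), config$enhancer_link_rate * 0.7)
    n_poised_link[prcr] <- rpois(length(prcr), 1.0)
    n_poised_link[prca] <- rpois(length(prca), 0.15)
    n_inter_link[c(prca, prcr, act)] <- rpois(length(c(prca, prcr, act)), 0.3)
    if (config$enhancer_kon_effect > 0) {
      mult <- 1 + config$enhancer_kon_effect * n_active_link
      idx <- prca
      kon_new <- k_on[idx] * mult[idx]
      s[idx] <- preserve_mean_s(s[idx], k_on[idx], kon_new, k_off[idx])
      k_on[idx] <- kon_new
    }

    # knockout: PRC targets burst more often -----------------------------
    k_on_dko <- k_on
    prc_targets <- classes %in% c("PRCa", "PRCr")
    k_on_dko[prc_targets] <- k_on[prc_targets] * config$dko_kon_multiplier

    # counts --------------------------------------------------------------
    cells <- sprintf("cell%03d", seq_len(config$n_cells))
    make_counts <- function(kon_vec) {
      sf <- rlnorm(config$n_cells, 0, config$size_factor_sdlog)
      sf <- sf / exp(mean(log(sf)))
      m <- matrix(0L, config$n_cells, n_genes, dimnames = list(cells, gene_id))
      for (g in seq_len(n_genes)) {
        p <- rbeta(config$n_cells, kon_vec[g], k_off[g])
        m[, g] <- rpois(config$n_cells, sf * s[g] * p)
      }
      list(cm = count_matrix(m), sf = sf)
    }
    wt <- make_counts(k_on)
    dko <- make_counts(k_on_dko)

    qc_table <- tibble(
      cell_id = cells,
      exon_reads = round(2e6 * wt$sf * runif(config$n_cells, 0.8, 1.2)),
      mito_fraction = runif(config$n_cells, 0.01, 0.08)
    )

    # contact network ------------------------------------------------------
    w_same <- 1 + config$contact_assortativity  # 0 => class-blind network
    n_cand <- config$n_contacts * 4
    ia <- sample.int(n_genes, n_cand, replace = TRUE)
    ib <- sample.int(n_genes, n_cand, replace = TRUE)
    ok <- ia != ib
    ia <- ia[ok]; ib <- ib[ok]
    wts <- ifelse(classes[ia] == classes[ib], w_same, 1)
    keep <- runif(length(ia)) < wts / max(wts)
    ia <- ia[keep]; ib <- ib[keep]
    n_use <- min(config$n_contacts, length(ia))
    ia <- ia[seq_len(n_use)]; ib <- ib[seq_len(n_use)]
    pp <- tibble(
      chr_a = chrom[ia], start_a = tss[ia] - 1000, end_a = tss[ia] + 1000,
      chr_b = chrom[ib], start_b = tss[ib] - 1000, end_b = tss[ib] + 1000,
      a_kind = "promoter", b_kind = "promoter",
      enhancer_class = NA_character_,
      genes_a = as.list(gene_id[ia]), genes_b = as.list(gene_id[ib])
    )

    # enhancer interaction records
    enh_rows <- list()
    add_enh <- function(gidx, n_links, cls) {
      for (i in gidx[n_links[gidx] > 0]) {
        for (k in seq_len(n_links[i])) {
          epos <- tss[i] + sample(c(-1, 1), 1) * round(runif(1, 5e4, 2e6))
          epos <- max(epos, 2000)
          enh_rows[[length(enh_rows) + 1]] <<- tibble(
            chr_a = chrom[i], start_a = tss[i] - 1000, end_a = tss[i] + 1000,
            chr_b = chrom[i], start_b = epos - 500, end_b = epos + 500,
            a_kind = "promoter", b_kind = "enhancer", enhancer_class = cls,
            genes_a = list(gene_id[i]), genes_b = list(character(0))
          )
        }
      }
    }
    add_enh(seq_len(n_genes), n_active_link, "active")
    add_enh(seq_len(n_genes), n_poised_link, "poised")
    add_enh(seq_len(n_genes), n_inter_link, "intermediate")
    interactions <- bind_rows(pp, bind_rows(enh_rows))
    class(interactions) <- c("interaction_set", class(interactions))

    links <- tibble(gene_id = gene_id, n_active = n_active_link,
                    n_intermediate = n_inter_link, n_poised = n_poised_link)

    truth <- list(
      params = tibble(gene_id = gene_id, class = classes,
                      k_on = k_on, k_off = k_off, s = s, k_on_dko = k_on_dko,
                      cluster = cluster_id),
      clusters = tibble(cluster = seq_len(placed)) |>
        mutate(genes = map(.data$cluster, ~ gene_id[which(cluster_id == .x)])),
      contacts = tibble(gene_a = gene_id[ia], gene_b = gene_id[ib]),
      size_factors_wt = setNames(wt$sf, cells),
      size_factors_dko = setNames(dko$sf, cells)
    )

    out <- list(wt = wt$cm, dko = dko$cm, annotation = annotation,
                states = states, interactions = interactions, links = links,
                qc_table = qc_table, truth = truth, config = config)
    if (!is.null(out_dir)) write_sim_dataset(out, out_dir)
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the exact file dialects the readers accept.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$wt, file.path(dir, "counts_wt.tsv"))
  write_count_matrix(sim$dko, file.path(dir, "counts_dko.tsv"))
  write_gene_annotation(sim$annotation, file.path(dir, "genes.bed"))
  readr::write_tsv(sim$states, file.path(dir, "chromatin_states.tsv"))
  write_interactions(sim$interactions, file.path(dir, "interactions.tsv"))
  readr::write_tsv(sim$links, file.path(dir, "enhancer_links.tsv"))
  readr::write_tsv(sim$qc_table, file.path(dir, "cell_qc.tsv"))
  readr::write_tsv(sim$truth$params, file.path(dir, "truth_params.tsv"))
  invisible(dir)
}
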