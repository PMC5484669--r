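# End-to-end orchestration: qc -> noise/kinetics -> clusters/proximity/
# contacts -> condition comparison, with serialized outputs and a manifest.

pipeline_defaults <- function() {
  list(
    counts = NULL, counts2 = NULL, qc_table = NULL, annotation = NULL,
    annotation_dialect = "bed6", states = NULL, interactions = NULL,
    decay = NULL, out_dir = NULL, seed = 1,
    stages = c("qc", "noise", "kinetics", "clusters", "proximity",
               "contacts", "compare"),
    exon_min = 5e5, mito_max = 0.10, amplification_z = NULL,
    min_mean = 10, dm_window = 50, bimodality = TRUE,
    kinetics_n_boot = 0, kinetics_min_cells = 30,
    neighborhood_windows = c(2e4, 5e4, 1e5, 2e5, 5e5),
    n_random_genomes = 100,
    cluster_window_size = 4, cluster_span_cap = 5e5,
    cluster_n_null = 1e5, cluster_q = 0.025,
    proximity_n_resamples = 10000,
    contacts_min_sep = 1e7, contacts_n_sets = 100, contacts_n_groups = 3,
    promoter_window = 2000
  )
}

stage_deps <- list(
  qc = character(0),
  noise = "qc",
  kinetics = "qc",
  clusters = "noise",
  proximity = character(0),
  contacts = "noise",
  compare = "noise"
)

load_or_pass <- function(x, loader) {
  if (is.null(x) || !is.character(x)) return(x)
  loader(x)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on the supplied inputs,
#' writes per-stage TSV/JSON outputs plus a manifest (effective
#' configuration, seed, package version, output checksums) to `out_dir`, and
#' returns all results. Reruns with the same configuration and seed are
#' reproducible. An enabled stage whose upstream stage is disabled raises a
#' dependency error.
#'
#' @param config named list; see `pipeline_defaults()` internals for the
#'   accepted keys — inputs (`counts`, `counts2`, `qc_table`, `annotation`,
#'   `states`, `interactions`, `decay` as paths or in-memory objects),
#'   `out_dir`, `seed`, `stages`, and per-stage thresholds. Unknown keys are
#'   rejected.
#' @return A named list of stage results, invisibly `NULL`-free; also written
#'   to `out_dir`.
#' @export
run_pipeline <- function(config) {
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defs, config)
  if (is.null(cfg$out_dir)) abort("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  for (st in stages) {
    missing_dep <- setdiff(stage_deps[[st]], stages)
    if (length(missing_dep) > 0) {
      abort(sprintf("stage '%s' requires disabled stage '%s'",
                    st, paste(missing_dep, collapse = ", ")))
    }
  }

  counts <- load_or_pass(cfg$counts, read_count_matrix)
  counts2 <- load_or_pass(cfg$counts2, read_count_matrix)
  annotation <- load_or_pass(cfg$annotation, function(p)
    read_gene_annotation(p, dialect = cfg$annotation_dialect))
  states <- load_or_pass(cfg$states, read_chromatin_states)
  qc_table <- load_or_pass(cfg$qc_table, function(p)
    readr::read_tsv(p, show_col_types = FALSE))
  interactions <- load_or_pass(cfg$interactions, function(p)
    read_interactions(p, annotation = annotation,
                      promoter_window = cfg$promoter_window))
  decay <- load_or_pass(cfg$decay, read_decay_table)

  seeds <- local_seed(cfg$seed, as.list(sample.int(2^30, 8)))
  res <- list()
  out_files <- character(0)
  emit_tsv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    flat <- df
    for (col in names(flat)) {
      if (is.list(flat[[col]])) {
        flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
      }
    }
    readr::write_tsv(flat, path)
    out_files <<- c(out_files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out_files <<- c(out_files, path)
  }

  norm2 <- NULL
  if ("qc" %in% stages) {
    qc <- qc_cells(counts, qc_table, exon_min = cfg$exon_min,
                   mito_max = cfg$mito_max,
                   amplification_z = cfg$amplification_z)
    emit_tsv(qc$report, "qc_report.tsv")
    norm <- size_factors(qc$counts)
    emit_tsv(tibble(cell_id = norm$cells, size_factor = norm$size_factors),
             "size_factors.tsv")
    expressed <- filter_expressed(norm, min_mean = cfg$min_mean)
    res$qc <- qc$report
    res$counts <- expressed
    if (!is.null(counts2)) {
      qc2 <- qc_cells(counts2, exon_min = 0)  # second condition: no qc table
      norm2 <- filter_expressed(size_factors(qc2$counts),
                                min_mean = cfg$min_mean)
      res$counts2 <- norm2
    }
  }

  if ("noise" %in% stages) {
    res$noise <- noise_profile(res$counts, annotation,
                               window_genes = cfg$dm_window,
                               bimodality = cfg$bimodality)
    emit_tsv(res$noise, "noise.tsv")
  }

  if ("kinetics" %in% stages) {
    res$kinetics <- fit_kinetics(res$counts, decay = decay,
                                 min_cells = cfg$kinetics_min_cells,
                                 n_boot = cfg$kinetics_n_boot,
                                 seed = seeds[[1]])
    emit_tsv(res$kinetics, "kinetics.tsv")
  }

  if ("clusters" %in% stages) {
    res$neighborhood <- neighborhood_noise_test(
      res$noise, annotation, window_bp = cfg$neighborhood_windows,
      n_random_genomes = cfg$n_random_genomes, seed = seeds[[2]])
    emit_tsv(res$neighborhood, "neighborhood.tsv")
    res$clusters <- call_noise_clusters(
      res$noise, annotation, window_size = cfg$cluster_window_size,
      span_cap = cfg$cluster_span_cap, n_null = cfg$cluster_n_null,
      q = cfg$cluster_q, seed = seeds[[3]])
    emit_tsv(res$clusters, "clusters.tsv")
    if (!is.null(states)) {
      enr <- cluster_mark_enrichment(
        res$clusters, semi_join(states, res$noise, by = "gene_id"))
      enr$p_adj <- stats::p.adjust(enr$p, method = "BH")
      res$cluster_enrichment <- enr
      emit_tsv(enr, "cluster_enrichment.tsv")
    }
  }

  if ("proximity" %in% stages && !is.null(states)) {
    sets <- split(states$gene_id, states$state)
    background <- unlist(sets[c("Active", "PRCa", "PRCr")], use.names = FALSE)
    res$proximity <- proximity_test(
      annotation, sets$PRCa, sets$PRCr, background,
      n_resamples = cfg$proximity_n_resamples, seed = seeds[[4]])
    emit_json(glance(res$proximity), "proximity.json")
  }

  if ("contacts" %in% stages && !is.null(interactions)) {
    lr <- filter_long_range(interactions, min_sep = cfg$contacts_min_sep)
    sets <- split(states$gene_id, states$state)
    res$contact_enrichment <- purrr::imap(
      sets[intersect(c("Active", "PRCa", "PRCr"), names(sets))],
      function(gs, nm) contact_enrichment(
        lr, gs, annotation, n_sets = cfg$contacts_n_sets,
        n_groups = cfg$contacts_n_groups, seed = seeds[[5]]))
    emit_json(purrr::map(res$contact_enrichment, glance), "contact_enrichment.json")
    res$class_preference <- promoter_class_preference(lr, states)
    emit_tsv(res$class_preference$preference, "class_preference.tsv")
    links <- enhancer_link_summary(interactions, annotation$gene_id)
    emit_tsv(links, "enhancer_links.tsv")
    res$enhancer_association <- enhancer_noise_association(
      links, res$noise, states)
    emit_json(res$enhancer_association, "enhancer_association.json")
  }

  if ("compare" %in% stages && !is.null(norm2)) {
    noise2 <- noise_profile(norm2, annotation, window_genes = cfg$dm_window,
                            bimodality = cfg$bimodality)
    ref <- res$noise
    per <- noise2
    if (!is.null(res$kinetics)) {
      ref <- left_join(ref, res$kinetics[, c("gene_id", "burst_freq")],
                       by = "gene_id")
      kin2 <- fit_kinetics(norm2, min_cells = cfg$kinetics_min_cells,
                           seed = seeds[[6]])
      per <- left_join(per, kin2[, c("gene_id", "burst_freq")], by = "gene_id")
    }
    res$compare <- class_shift_tests(ref, per, states)
    res$compare$tests$p_adj <- stats::p.adjust(res$compare$tests$p, "BH")
    emit_tsv(res$compare$tests, "compare_tests.tsv")
    emit_tsv(res$compare$per_gene, "compare_per_gene.tsv")
  }

  manifest <- list(
    package = "burstnoise",
    version = as.character(utils::packageVersion("burstnoise")),
    seed = cfg$seed,
    stage_seeds = unlist(seeds),
    stages = stages,
    config = cfg[setdiff(names(cfg), c("counts", "counts2", "qc_table",
                                       "annotation", "states", "interactions",
                                       "decay"))],
    checksums = as.list(tools::md5sum(out_files))
  )
  emit_json(manifest, "manifest.json")
  invisible(res)
}
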