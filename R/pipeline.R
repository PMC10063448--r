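#' Pipeline configuration
#'
#' Collects every stage's inputs and tunables: paths to contig, count and
#' cohort inputs (ignored under `demo`), QC thresholds, clustering
#' parameters, signature size, network threshold, survival horizon, demo
#' scale and the single global seed (fanned out to per-stage seeds by fixed
#' offsets).
#'
#' @param contigs_path,contigs_dialect Contig table location and dialect.
#' @param counts_dir MTX directory for the count matrix.
#' @param meta_path Per-cell metadata TSV (cell_id, sample, batch, lineage).
#' @param cohort_path Bulk cohort TSV.
#' @param qc A [qc_thresholds()].
#' @param resolution,n_neighbors,n_pcs,n_hvg Clustering parameters.
#' @param signature_k Signature size (default 20).
#' @param network_threshold CDR3 edit-distance threshold (default 0).
#' @param survival_horizon Truncation for the survival analysis, months.
#' @param demo_n_cells,demo_n_genes,demo_n_samples Demo-run scale.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(contigs_path = NULL,
                            contigs_dialect = "tenx_csv",
                            counts_dir = NULL,
                            meta_path = NULL,
                            cohort_path = NULL,
                            qc = qc_thresholds(),
                            resolution = 0.6,
                            n_neighbors = 15,
                            n_pcs = 30,
                            n_hvg = 1000,
                            signature_k = 20,
                            network_threshold = 0,
                            survival_horizon = 60,
                            demo_n_cells = 2000,
                            demo_n_genes = 1000,
                            demo_n_samples = 200,
                            seed = 1L) {
  structure(
    list(
      contigs_path = contigs_path, contigs_dialect = contigs_dialect,
      counts_dir = counts_dir, meta_path = meta_path,
      cohort_path = cohort_path, qc = qc, resolution = resolution,
      n_neighbors = n_neighbors, n_pcs = n_pcs, n_hvg = n_hvg,
      signature_k = signature_k, network_threshold = network_threshold,
      survival_horizon = survival_horizon,
      demo_n_cells = demo_n_cells, demo_n_genes = demo_n_genes,
      demo_n_samples = demo_n_samples, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected with an error naming them.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the full pipeline
#'
#' Chains every stage: contig processing, clonotype and diversity analysis,
#' the CDR3 network, the expression pipeline with signature derivation, and
#' cohort scoring with survival and response association. With `demo = TRUE`
#' the inputs are generated by the synthetic-data module at the configured
#' demo scale (ignoring the path fields); otherwise every path must exist.
#' All stage artifacts are written under `out_dir` along with a
#' `manifest.json` recording parameters and the MD5 digest of every output,
#' so two runs with the same seed produce byte-identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param demo Generate synthetic inputs instead of reading paths.
#' @return Invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, demo = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)

  if (demo) {
    rep_cfg <- repertoire_sim_config(
      n_cells = config$demo_n_cells,
      frac_unproductive = 0.05, frac_orphan_gamma = 0.02,
      frac_orphan_delta = 0.02, seed = seed + 1L
    )
    sim <- simulate_repertoire(rep_cfg)
    contigs_path <- file.path(out_dir, "demo_contigs.csv")
    write_contigs_tenx(sim$contigs, contigs_path)
    outputs <- c(outputs, contigs_path)

    expr_cfg <- expression_sim_config(
      n_cells = nrow(sim$truth), n_genes = config$demo_n_genes,
      n_clusters = 3,
      vd_marker_genes = c(TRDV1 = 1L, TRDV2 = 2L, TRDV3 = 3L),
      signature_effect = 1.5, seed = seed + 2L
    )
    expr_sim <- simulate_expression(expr_cfg, cell_ids = sim$truth$barcode)
    counts <- expr_sim$counts
    cell_meta <- expr_sim$cell_meta %>%
      mutate(sample_id = "S1", batch = "B1")

    cohort_cfg <- cohort_sim_config(
      n_samples = config$demo_n_samples,
      hazard_ratio_per_sd = 0.6, response_logit_slope = 0.8,
      signature_genes = expr_cfg$planted_signature_genes,
      seed = seed + 3L
    )
    cohort <- simulate_cohort(cohort_cfg)
  } else {
    for (f in c("contigs_path", "counts_dir", "meta_path", "cohort_path")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        abort(paste0("missing or nonexistent input for `", f,
                     "`; supply it or use demo = TRUE."))
      }
    }
    contigs_path <- config$contigs_path
    counts <- read_counts_mtx(config$counts_dir)
    cell_meta <- readr::read_tsv(config$meta_path, show_col_types = FALSE)
    cohort <- readr::read_tsv(config$cohort_path, show_col_types = FALSE)
  }

  # --- contig processing -------------------------------------------------
  contigs <- read_contigs(contigs_path, dialect = config$contigs_dialect)
  filtered <- filter_productive(contigs)
  reassigned <- reassign_hybrid_delta(filtered)
  selected <- select_cell_chains(reassigned)
  paired <- pair_cells(selected)
  outputs <- c(
    outputs,
    .write_tsv(paired, out_dir, "paired_cells.tsv"),
    .write_tsv(productive_audit(filtered), out_dir, "contig_audit.tsv"),
    .write_tsv(orphan_cells(paired), out_dir, "orphan_cells.tsv")
  )

  # --- clonotypes and diversity ------------------------------------------
  cells <- label_expansion(call_clonotypes(paired))
  usage <- chain_usage_table(cells)
  gini <- cells %>%
    group_by(.data$sample_id) %>%
    summarise(
      gini = gini_coefficient(as.integer(table(.data$clonotype_key))),
      .groups = "drop"
    )
  outputs <- c(
    outputs,
    .write_tsv(cells, out_dir, "clonotype_cells.tsv"),
    .write_tsv(expansion_summary(cells, "vd2_status"), out_dir,
               "expansion_by_vd2.tsv"),
    .write_tsv(usage, out_dir, "chain_usage.tsv"),
    .write_tsv(gini, out_dir, "gini_by_sample.tsv")
  )

  # --- expression pipeline ------------------------------------------------
  x <- gdx(counts, cell_meta = dplyr::rename(cell_meta, cell_id = 1)) %>%
    qc_filter(config$qc) %>%
    normalize_log() %>%
    cluster_cells(
      resolution = config$resolution, n_neighbors = config$n_neighbors,
      n_pcs = config$n_pcs, n_hvg = config$n_hvg, seed = seed + 4L
    ) %>%
    assign_vd2_labels()
  vd2neg <- !is.na(x$cells$vd2_status) & x$cells$vd2_status == "Vd2neg"
  refmask <- !is.na(x$cells$vd2_status) & x$cells$vd2_status == "Vd2pos"
  de <- wilcoxon_de(x, vd2neg, refmask)
  sig <- derive_signature(de, k = config$signature_k,
                          contrast = "Vd2neg vs reference")
  score <- gene_set_score(x, sig$gene, seed = seed + 5L)
  x$cells$signature_score <- unname(score[x$cells$cell_id])
  sig_path <- file.path(out_dir, "signature.json")
  write_signature(sig, sig_path)
  outputs <- c(
    outputs,
    .write_tsv(x$cells, out_dir, "expression_cells.tsv"),
    .write_tsv(de, out_dir, "differential_expression.tsv"),
    sig_path
  )

  # --- CDR3 network -------------------------------------------------------
  net_cells <- cells %>%
    left_join(
      x$cells %>% select(barcode = "cell_id", phenotype_cluster = "leiden_cluster"),
      by = "barcode"
    )
  net <- build_network(net_cells, threshold = config$network_threshold)
  outputs <- c(
    outputs,
    .write_tsv(net$edges, out_dir, "network_edges.tsv"),
    .write_tsv(network_stats(net), out_dir, "network_stats.tsv")
  )

  # --- cohort scoring -----------------------------------------------------
  scored <- sample_signature_score(cohort, sig)
  scored$group <- median_split(scored$score)
  surv <- truncate_survival(scored$time, scored$event,
                            horizon = config$survival_horizon)
  km <- kaplan_meier(surv$time, surv$event, group = scored$group)
  lr <- logrank_test(surv$time, surv$event, scored$group)
  ra <- response_association(scored$score, scored$response)
  results <- list(
    signature_overlap = attr(scored, "n_overlap"),
    logrank = as.list(lr),
    response = as.list(ra)
  )
  json_path <- file.path(out_dir, "cohort_tests.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(
    outputs,
    .write_tsv(scored, out_dir, "cohort_scores.tsv"),
    .write_tsv(tidy(km), out_dir, "survival_curves.tsv"),
    json_path
  )

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    seed = seed,
    demo = demo,
    parameters = list(
      resolution = config$resolution, n_neighbors = config$n_neighbors,
      n_pcs = config$n_pcs, n_hvg = config$n_hvg,
      signature_k = config$signature_k,
      network_threshold = config$network_threshold,
      survival_horizon = config$survival_horizon,
      qc = unclass(config$qc),
      demo_scale = list(n_cells = config$demo_n_cells,
                        n_genes = config$demo_n_genes,
                        n_samples = config$demo_n_samples)
    ),
    outputs = lapply(
      setNames(outputs, basename(outputs)),
      function(p) unname(tools::md5sum(p))
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(
    manifest = manifest, cells = cells, usage = usage, gini = gini,
    expression = x, de = de, signature = sig, network = net,
    cohort_scores = scored, logrank = lr, response = ra
  ))
}
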