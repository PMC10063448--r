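#' Configure a synthetic single-cell count matrix
#'
#' Configuration for [simulate_expression()]. Counts are negative binomial
#' around cluster-specific gene means; Vdelta marker genes are elevated only
#' in their assigned cluster, and a designated subpopulation carries a
#' log-scale shift on the planted signature genes.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_clusters Number of planted subpopulations (roughly equal sizes).
#' @param nb_mean Baseline negative-binomial mean per gene (genes get
#'   lognormal variation around it).
#' @param nb_dispersion NB size parameter; larger means closer to Poisson.
#' @param planted_signature_genes Gene names carrying the signature shift;
#'   must fit inside the gene universe.
#' @param signature_effect Log-fold shift (natural log) applied to signature
#'   genes in the signature-bearing subpopulation (cluster 1 by convention).
#' @param vd_marker_genes Named integer vector mapping Vdelta gene names to
#'   the cluster in which they are expressed (elsewhere near zero).
#' @param marker_effect Log-fold elevation of a Vdelta marker in its cluster.
#' @param batch_labels Optional per-cell batch factor (length `n_cells`) or a
#'   number of batches to assign round-robin; batches get additive per-gene
#'   log shifts.
#' @param batch_effect_sd SD of the per-gene additive batch shift (log scale).
#' @param mito_frac Fraction of genes named with the `MT-` prefix so QC has
#'   mitochondrial content to measure.
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_cells = 500,
                                  n_genes = 1000,
                                  n_clusters = 2,
                                  nb_mean = 2,
                                  nb_dispersion = 2,
                                  planted_signature_genes = paste0("SIG", seq_len(25)),
                                  signature_effect = 1,
                                  vd_marker_genes = c(TRDV1 = 1L, TRDV2 = 2L),
                                  marker_effect = 3,
                                  batch_labels = NULL,
                                  batch_effect_sd = 0,
                                  mito_frac = 0.02,
                                  seed = 1L) {
  if (n_genes < length(planted_signature_genes)) {
    abort("`n_genes` is smaller than the planted signature gene set.")
  }
  if (!is.finite(signature_effect)) abort("`signature_effect` must be finite.")
  if (nb_mean <= 0 || nb_dispersion <= 0) abort("NB parameters must be positive.")
  if (n_clusters < 1) abort("`n_clusters` must be >= 1.")
  if (length(vd_marker_genes) && any(vd_marker_genes > n_clusters)) {
    abort("`vd_marker_genes` assigns a marker to a nonexistent cluster.")
  }
  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      n_clusters = as.integer(n_clusters), nb_mean = nb_mean,
      nb_dispersion = nb_dispersion,
      planted_signature_genes = planted_signature_genes,
      signature_effect = signature_effect,
      vd_marker_genes = vd_marker_genes, marker_effect = marker_effect,
      batch_labels = batch_labels, batch_effect_sd = batch_effect_sd,
      mito_frac = mito_frac, seed = as.integer(seed)
    ),
    class = "expression_sim_config"
  )
}

#' Simulate a single-cell count matrix with planted structure
#'
#' @param config An [expression_sim_config()].
#' @param cell_ids Optional barcodes to use as cell identifiers (length
#'   `n_cells`); defaults to `CELL%05d`.
#' @param lineage Optional per-cell lineage labels (e.g. `"gd"`, `"CD4"`,
#'   `"CD8"`) recorded in the metadata; recycled to `n_cells`.
#' @return A list with `counts` (genes x cells sparse dgCMatrix), `cell_meta`
#'   (tibble: cell_id, true_cluster, batch, lineage, signature_bearing) and
#'   `gene_meta` (tibble: gene, is_signature, marker_cluster).
#' @export
simulate_expression <- function(config, cell_ids = NULL, lineage = "gd") {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    nc <- config$n_cells
    sig <- config$planted_signature_genes
    n_mito <- max(0L, round(config$mito_frac * ng) - 0L)
    n_named <- length(sig) + length(config$vd_marker_genes) + n_mito
    if (n_named > ng) abort("gene universe too small for named genes.")
    genes <- c(
      sig, names(config$vd_marker_genes),
      if (n_mito > 0) sprintf("MT-G%02d", seq_len(n_mito)),
      sprintf("GENE%05d", seq_len(ng - n_named))
    )
    cells <- cell_ids %||% sprintf("CELL%05d", seq_len(nc))
    if (length(cells) != nc) abort("`cell_ids` must have length `n_cells`.")

    clusters <- rep_len(seq_len(config$n_clusters), nc)
    batch <- if (is.null(config$batch_labels)) {
      rep("B1", nc)
    } else if (length(config$batch_labels) == 1 && is.numeric(config$batch_labels)) {
      # random assignment, so batch is not confounded with the planted clusters
      paste0("B", sample(rep_len(seq_len(config$batch_labels), nc)))
    } else {
      as.character(rep_len(config$batch_labels, nc))
    }

    # log-scale mean model: gene baseline + cluster wiggle + planted effects
    base <- log(config$nb_mean) + rnorm(ng, 0, 0.3)
    logmu <- matrix(base, ng, config$n_clusters)
    logmu <- logmu + matrix(rnorm(ng * config$n_clusters, 0, 0.1), ng)
    for (g in names(config$vd_marker_genes)) {
      k <- config$vd_marker_genes[[g]]
      i <- match(g, genes)
      logmu[i, ] <- log(0.05)              # near-silent off-cluster
      logmu[i, k] <- log(0.05) + config$marker_effect + log(config$nb_mean / 0.05)
    }
    # signature genes carry exactly the configured shift and no cluster wiggle,
    # so the null (effect = 0) is exactly flat across subpopulations
    sig_idx <- match(sig, genes)
    if (length(sig_idx)) {
      logmu[sig_idx, ] <- base[sig_idx]
      logmu[sig_idx, 1L] <- base[sig_idx] + config$signature_effect
    }

    batch_shift <- matrix(0, ng, length(unique(batch)),
                          dimnames = list(NULL, unique(batch)))
    if (config$batch_effect_sd > 0 && ncol(batch_shift) > 1) {
      batch_shift[] <- rnorm(length(batch_shift), 0, config$batch_effect_sd)
      batch_shift[, 1] <- 0
    }

    mu <- exp(logmu[, clusters, drop = FALSE] + batch_shift[, batch, drop = FALSE])
    counts <- matrix(
      rnbinom(ng * nc, mu = as.vector(mu), size = config$nb_dispersion),
      nrow = ng, dimnames = list(genes, cells)
    )
    list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cell_meta = tibble(
        cell_id = cells,
        true_cluster = clusters,
        batch = batch,
        lineage = rep_len(lineage, nc),
        signature_bearing = clusters == 1L
      ),
      gene_meta = tibble(
        gene = genes,
        is_signature = genes %in% sig,
        marker_cluster = unname(config$vd_marker_genes[match(genes, names(config$vd_marker_genes))])
      )
    )
  })
}
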