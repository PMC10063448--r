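#' Single-cell expression container
#'
#' A light container holding a genes x cells count matrix, an optional
#' log-normalized layer, and per-cell / per-gene metadata tibbles. All
#' pipeline stages take and return a `gdx`.
#'
#' @param counts Genes x cells matrix (dense or sparse) with dimnames.
#' @param cell_meta Optional tibble with a `cell_id` column matching the
#'   matrix columns.
#' @param gene_meta Optional tibble with a `gene` column matching the rows.
#' @return A `gdx` object.
#' @export
gdx <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene rownames and cell colnames.")
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  cells <- cell_meta %||% tibble(cell_id = colnames(counts))
  if (!"cell_id" %in% names(cells)) abort("`cell_meta` needs a `cell_id` column.")
  cells <- cells[match(colnames(counts), cells$cell_id), , drop = FALSE]
  genes <- gene_meta %||% tibble(gene = rownames(counts))
  if (!"gene" %in% names(genes)) abort("`gene_meta` needs a `gene` column.")
  genes <- genes[match(rownames(counts), genes$gene), , drop = FALSE]
  structure(
    list(counts = counts, logcounts = NULL, cells = as_tibble(cells),
         genes = as_tibble(genes)),
    class = "gdx"
  )
}

#' @export
print.gdx <- function(x, ...) {
  cat("gdx: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells",
      if (!is.null(x$logcounts)) " (log-normalized layer present)", "\n",
      sep = "")
  cat("  cell metadata: ", paste(names(x$cells), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy gdx
#' @export
tidy.gdx <- function(x, ...) x$cells

#' Quality-control thresholds
#'
#' Defaults follow strict `<` comparisons: cells with fewer than `min_genes`
#' detected genes are removed first, then genes detected in fewer than
#' `min_cells_per_gene` cells; surviving cells must then have fewer than
#' `max_genes` genes, fewer than `max_counts` total counts and less than
#' `max_pct_mito` percent mitochondrial counts.
#'
#' @param min_genes,min_cells_per_gene,max_genes,max_counts,max_pct_mito
#'   Positive thresholds (defaults 200, 3, 4000, 20000, 10).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, min_cells_per_gene = 3,
                          max_genes = 4000, max_counts = 20000,
                          max_pct_mito = 10) {
  vals <- c(min_genes, min_cells_per_gene, max_genes, max_counts, max_pct_mito)
  if (any(vals <= 0)) abort("all QC thresholds must be positive.")
  structure(
    list(min_genes = min_genes, min_cells_per_gene = min_cells_per_gene,
         max_genes = max_genes, max_counts = max_counts,
         max_pct_mito = max_pct_mito),
    class = "qc_thresholds"
  )
}

#' Filter cells and genes on quality-control thresholds
#'
#' Stage order is fixed: (1) drop cells below the gene-detection floor,
#' (2) drop genes detected in too few cells, (3) drop cells violating the
#' upper bounds (strict `<` on genes, counts and mitochondrial percentage).
#' Per-stage removal counts are attached as the `"qc_audit"` attribute.
#'
#' @param x A [gdx()] (or a genes x cells matrix).
#' @param thresholds A [qc_thresholds()].
#' @param mito_pattern Regex identifying mitochondrial genes (default
#'   `"^MT-"`).
#' @return The filtered `gdx` with `n_genes`, `total_counts` and `pct_mito`
#'   added to the cell metadata.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds(), mito_pattern = "^MT-") {
  if (!inherits(x, "gdx")) x <- gdx(x)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  m <- x$counts
  audit <- list()

  genes_per_cell <- Matrix::colSums(m > 0)
  keep1 <- genes_per_cell >= thresholds$min_genes
  audit$cells_below_min_genes <- sum(!keep1)
  if (!any(keep1)) abort("QC removed all cells at the min-genes stage.")
  m <- m[, keep1, drop = FALSE]

  cells_per_gene <- Matrix::rowSums(m > 0)
  keepg <- cells_per_gene >= thresholds$min_cells_per_gene
  audit$genes_below_min_cells <- sum(!keepg)
  m <- m[keepg, , drop = FALSE]

  n_genes <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito <- grepl(mito_pattern, rownames(m))
  pct_mito <- if (any(mito)) {
    100 * Matrix::colSums(m[mito, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(m))
  }
  keep2 <- n_genes < thresholds$max_genes & total < thresholds$max_counts &
    pct_mito < thresholds$max_pct_mito
  audit$cells_above_upper_bounds <- sum(!keep2)
  if (!any(keep2)) abort("QC removed all cells at the upper-bounds stage.")
  m <- m[, keep2, drop = FALSE]

  out <- x
  out$counts <- m
  out$logcounts <- NULL
  out$cells <- x$cells[match(colnames(m), x$cells$cell_id), , drop = FALSE] %>%
    mutate(n_genes = n_genes[keep2], total_counts = total[keep2],
           pct_mito = pct_mito[keep2])
  out$genes <- x$genes[match(rownames(m), x$genes$gene), , drop = FALSE]
  attr(out, "qc_audit") <- as_tibble(audit)
  out
}

#' Library-size normalize and log-transform
#'
#' Scales each cell to `target_sum` total counts and applies the natural
#' `log(1 + x)` transform; the result is stored as the `logcounts` layer.
#'
#' @param x A QC-filtered [gdx()].
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return The `gdx` with a `logcounts` layer.
#' @export
normalize_log <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "gdx"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) abort("zero-count cell encountered; run qc_filter() first.")
  sf <- target_sum / totals
  x$logcounts <- log1p(x$counts %*% Matrix::Diagonal(x = sf))
  dimnames(x$logcounts) <- dimnames(x$counts)
  x
}

#' Batch adjustment by per-gene location equalization
#'
#' Centres each gene within batch on the log layer and restores the gene's
#' grand mean, removing additive batch shifts while leaving within-batch
#' contrasts untouched. Optionally also equalizes per-batch scale.
#'
#' @param x A normalized [gdx()].
#' @param batch Column name in the cell metadata holding batch labels
#'   (default `"batch"`).
#' @param scale Also divide by the within-batch SD and restore the pooled SD.
#' @return The `gdx` with adjusted `logcounts` (dense after adjustment).
#' @export
batch_adjust <- function(x, batch = "batch", scale = FALSE) {
  stopifnot(inherits(x, "gdx"))
  if (is.null(x$logcounts)) abort("run normalize_log() before batch_adjust().")
  labs <- x$cells[[batch]]
  if (is.null(labs)) abort(paste0("cell metadata has no `", batch, "` column."))
  if (length(unique(labs)) < 2) {
    warn("single batch; batch_adjust() is the identity.")
    return(x)
  }
  m <- as.matrix(x$logcounts)
  grand <- rowMeans(m)
  pooled_sd <- apply(m, 1, sd)
  for (b in unique(labs)) {
    j <- labs == b
    mu <- rowMeans(m[, j, drop = FALSE])
    m[, j] <- m[, j] - mu
    if (scale) {
      s <- apply(m[, j, drop = FALSE], 1, sd)
      s[s == 0] <- 1
      m[, j] <- m[, j] / s * ifelse(pooled_sd == 0, 1, pooled_sd)
    }
    m[, j] <- m[, j] + grand
  }
  x$logcounts <- m
  x
}

.select_hvg <- function(m, n_hvg) {
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowMeans(m^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  head(order(disp, decreasing = TRUE), min(n_hvg, nrow(m)))
}

#' Cluster cells with the Leiden algorithm
#'
#' Dispersion-ranked highly variable genes are scaled, reduced by PCA, a
#' k-nearest-neighbour graph is built in PC space, and Leiden community
#' detection (modularity objective) is run at the given resolution.
#' Deterministic under a fixed seed.
#'
#' @param x Normalized [gdx()].
#' @param resolution Leiden resolution parameter (default 0.6).
#' @param n_neighbors kNN graph degree (default 15).
#' @param n_pcs Number of principal components (default 30).
#' @param n_hvg Number of highly variable genes (default 1000).
#' @param seed Integer seed.
#' @return The `gdx` with an integer `leiden_cluster` column in the cell
#'   metadata (clusters numbered from 1 by decreasing size).
#' @export
cluster_cells <- function(x, resolution = 0.6, n_neighbors = 15, n_pcs = 30,
                          n_hvg = 1000, seed = 0L) {
  stopifnot(inherits(x, "gdx"))
  if (is.null(x$logcounts)) abort("run normalize_log() before cluster_cells().")
  nc <- ncol(x$counts)
  if (nc <= n_neighbors) abort("fewer cells than `n_neighbors`.")
  with_seed(seed, {
    hvg <- .select_hvg(x$logcounts, n_hvg)
    m <- as.matrix(x$logcounts[hvg, , drop = FALSE])
    keep <- apply(m, 1, sd) > 0
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2) {
      # degenerate: no variable genes, everything is one cluster
      x$cells$leiden_cluster <- 1L
      return(x)
    }
    m <- t(scale(t(m)))
    pcs <- prcomp(t(m), center = FALSE, scale. = FALSE,
                  rank. = min(n_pcs, nrow(m) - 1, nc - 1))$x
    d <- as.matrix(stats::dist(pcs))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(n_neighbors)])
    edges <- cbind(rep(seq_len(nc), each = n_neighbors), as.vector(nn))
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    comm <- igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5
    )
    memb <- igraph::membership(comm)
    ord <- order(table(memb), decreasing = TRUE)
    relabel <- match(memb, as.integer(names(table(memb))[ord]))
    x$cells$leiden_cluster <- as.integer(relabel)
    x
  })
}

.default_vd_genes <- c("TRDV1", "TRDV2", "TRDV3", .default_hybrid_genes)

#' Assign Vdelta2 labels from Vdelta gene expression
#'
#' Each cell is labelled by the most strongly expressed Vdelta gene:
#' `"Vd2pos"` if the argmax is TRDV2, `"Vd2neg"` otherwise. Cells with
#' all-zero Vdelta expression, or a tie involving TRDV2 and a non-TRDV2
#' gene, are left unassigned (`NA`).
#'
#' @param x Normalized [gdx()].
#' @param vd_genes Candidate Vdelta genes (default: TRDV1/2/3 plus the five
#'   hybrid TRAV/DV genes).
#' @return The `gdx` with a `vd2_status` cell-metadata column.
#' @export
assign_vd2_labels <- function(x, vd_genes = .default_vd_genes) {
  stopifnot(inherits(x, "gdx"))
  layer <- x$logcounts %||% x$counts
  present <- intersect(vd_genes, rownames(layer))
  if (!length(present)) abort("none of the Vdelta genes are present in the matrix.")
  m <- as.matrix(layer[present, , drop = FALSE])
  top <- apply(m, 2, max)
  n_top <- apply(m, 2, function(v) sum(v == max(v)))
  arg <- present[apply(m, 2, which.max)]
  status <- ifelse(.norm_gene(arg) == "TRDV2", "Vd2pos", "Vd2neg")
  status[top == 0] <- NA            # no Vdelta expression at all
  status[n_top > 1] <- NA           # ambiguous argmax
  x$cells$vd2_status <- status
  x
}

#' Control-matched gene-set score
#'
#' Per-cell mean expression of the gene set minus the mean expression of a
#' control set sampled, within expression-magnitude bins, to match the set's
#' expression profile. Genes are binned by average expression across cells
#' into `n_bins` equal-size bins; for every set gene, `ctrl_size` control
#' genes are drawn (without replacement where possible) from its bin,
#' excluding set genes.
#'
#' @param x Normalized [gdx()].
#' @param gene_set Character vector of genes; the overlap with the matrix is
#'   reported via the `"n_overlap"` attribute and must be non-empty.
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_size Controls sampled per set gene (default 50).
#' @param seed Integer seed for control sampling.
#' @return Named numeric vector of per-cell scores (attribute `n_overlap`).
#' @export
gene_set_score <- function(x, gene_set, n_bins = 25, ctrl_size = 50, seed = 0L) {
  stopifnot(inherits(x, "gdx"))
  layer <- x$logcounts %||% x$counts
  set <- intersect(unique(gene_set), rownames(layer))
  if (!length(set)) abort("gene set has no overlap with the matrix.")
  with_seed(seed, {
    avg <- Matrix::rowMeans(layer)
    bins <- cut(rank(avg, ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    names(bins) <- rownames(layer)
    ctrl <- character(0)
    for (b in unique(bins[set])) {
      pool <- setdiff(names(bins)[bins == b], set)
      want <- ctrl_size * sum(bins[set] == b)
      if (length(pool)) {
        ctrl <- c(ctrl, sample(pool, min(want, length(pool))))
      }
    }
    ctrl <- unique(ctrl)
    set_mean <- Matrix::colMeans(layer[set, , drop = FALSE])
    ctrl_mean <- if (length(ctrl)) {
      Matrix::colMeans(layer[ctrl, , drop = FALSE])
    } else {
      rep(0, ncol(layer))
    }
    score <- set_mean - ctrl_mean
    names(score) <- colnames(layer)
    attr(score, "n_overlap") <- length(set)
    score
  })
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided rank-sum test (normal approximation with tie
#' correction) of target versus reference cells on the log layer, with
#' Benjamini-Hochberg adjustment across genes. The log fold change is
#' `log(mean(expm1(target)) + eps) - log(mean(expm1(reference)) + eps)`
#' (natural log, `eps = 1e-9`); a display copy is clipped to +/-7.
#'
#' @param x Normalized [gdx()].
#' @param target,reference Logical masks over cells, or character cell ids;
#'   must be disjoint and non-empty.
#' @return A `gdtcr_de` tibble: `gene`, `statistic` (rank-sum U), `z`,
#'   `p_value`, `p_adj`, `logfc`, `logfc_display`, `direction`.
#' @export
wilcoxon_de <- function(x, target, reference) {
  stopifnot(inherits(x, "gdx"))
  if (is.null(x$logcounts)) abort("run normalize_log() before wilcoxon_de().")
  as_mask <- function(sel) {
    if (is.logical(sel)) {
      if (length(sel) != ncol(x$counts)) abort("mask length must equal cell count.")
      sel
    } else {
      colnames(x$counts) %in% sel
    }
  }
  tm <- as_mask(target)
  rm_ <- as_mask(reference)
  if (!any(tm) || !any(rm_)) abort("target and reference groups must be non-empty.")
  if (any(tm & rm_)) abort("target and reference groups overlap.")
  m <- as.matrix(x$logcounts[, tm | rm_, drop = FALSE])
  in_t <- tm[tm | rm_]
  n1 <- sum(in_t); n2 <- sum(!in_t); n <- n1 + n2
  rk <- t(apply(m, 1, rank))
  r1 <- rowSums(rk[, in_t, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(m, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
  p <- 2 * pnorm(-abs(z))
  eps <- 1e-9
  mt <- rowMeans(expm1(m[, in_t, drop = FALSE]))
  mr <- rowMeans(expm1(m[, !in_t, drop = FALSE]))
  lfc <- log(mt + eps) - log(mr + eps)
  out <- tibble(
    gene = rownames(m),
    statistic = unname(u), z = unname(z), p_value = unname(p),
    p_adj = unname(p.adjust(p, method = "BH")),
    logfc = unname(lfc),
    logfc_display = pmin(pmax(lfc, -7), 7),
    direction = ifelse(z > 0, "up", ifelse(z < 0, "down", "none"))
  )
  class(out) <- c("gdtcr_de", class(out))
  out
}

#' Derive a top-k upregulated gene signature
#'
#' Keeps genes upregulated in the target group, orders by ascending raw
#' p-value with ties broken by larger log fold change and then gene name,
#' and returns the top `k` (all, with a warning, if fewer exist).
#'
#' @param de A [wilcoxon_de()] result.
#' @param k Signature size (default 20).
#' @param contrast Free-text provenance note stored on the signature.
#' @return A `gene_signature` tibble (the selected rows of `de`, in rank
#'   order) with a `contrast` attribute.
#' @export
derive_signature <- function(de, k = 20, contrast = "") {
  up <- de %>%
    filter(.data$direction == "up") %>%
    arrange(.data$p_value, desc(.data$logfc), .data$gene)
  if (nrow(up) < k) {
    warn(sprintf("only %d upregulated genes available (k = %d); returning all.",
                 nrow(up), k))
  }
  sig <- head(up, k)
  attr(sig, "contrast") <- contrast
  class(sig) <- c("gene_signature", class(de))
  sig
}

#' @method glance gdtcr_de
#' @export
glance.gdtcr_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_sig_up = sum(x$p_adj < 0.05 & x$logfc > 0.4),
    n_sig_down = sum(x$p_adj < 0.05 & x$logfc < -0.4)
  )
}

#' Write / read a gene signature as JSON
#'
#' @param signature A [derive_signature()] result.
#' @param path JSON path.
#' @return `path` (writer) / a `gene_signature` tibble (reader).
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(contrast = attr(signature, "contrast") %||% "",
         genes = as.data.frame(signature)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- as_tibble(obj$genes)
  attr(sig, "contrast") <- obj$contrast
  class(sig) <- c("gene_signature", class(sig))
  sig
}
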