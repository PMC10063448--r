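#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between amino-acid strings,
#' vectorized elementwise with recycling.
#'
#' @param a,b Character vectors (empty strings allowed).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(adist(a[i], b[i])[1, 1])
  out
}

#' Build per-patient CDR3 similarity networks
#'
#' Cells are nodes; two cells of the same patient are connected when the
#' Levenshtein distance between their delta-chain CDR3 amino-acid sequences
#' is at most `threshold` (default 0: identical sequences only). Cells
#' without a phenotype cluster label are excluded before building. Networks
#' are built strictly within patient; no cross-patient edges exist.
#'
#' @param cells Cell tibble with `sample_id` (patient), `barcode`,
#'   `delta_cdr3_aa` and `phenotype_cluster`.
#' @param threshold Maximum edit distance for an edge (default 0).
#' @return A `repertoire_network` object: list with `nodes` (tibble:
#'   `patient_id`, `cell_id`, `delta_cdr3_aa`, `component`,
#'   `component_size`) and `edges` (tibble: `patient_id`, `cell_a`,
#'   `cell_b`, `distance`).
#' @export
build_network <- function(cells, threshold = 0L) {
  need <- c("sample_id", "barcode", "delta_cdr3_aa", "phenotype_cluster")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    abort(paste0("`cells` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  eligible <- cells %>% filter(!is.na(.data$phenotype_cluster))
  empty_pat <- setdiff(unique(cells$sample_id), unique(eligible$sample_id))
  if (length(empty_pat)) {
    warn(paste0("patient(s) with no eligible cells: ",
                paste(empty_pat, collapse = ", ")))
  }
  nodes_list <- list()
  edges_list <- list()
  for (pat in unique(eligible$sample_id)) {
    sub <- eligible[eligible$sample_id == pat, , drop = FALSE]
    ids <- sub$barcode
    m <- length(ids)
    dmat <- adist(sub$delta_cdr3_aa)
    adj <- dmat <= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    sizes <- as.integer(table(comp$membership))
    nodes_list[[pat]] <- tibble(
      patient_id = pat, cell_id = ids,
      delta_cdr3_aa = sub$delta_cdr3_aa,
      component = as.integer(comp$membership),
      component_size = sizes[comp$membership]
    )
    if (m > 1) {
      idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
      if (nrow(idx)) {
        edges_list[[pat]] <- tibble(
          patient_id = pat,
          cell_a = ids[idx[, 1]], cell_b = ids[idx[, 2]],
          distance = dmat[idx]
        )
      }
    }
  }
  structure(
    list(
      nodes = bind_rows(nodes_list) %||% tibble(),
      edges = if (length(edges_list)) bind_rows(edges_list) else
        tibble(patient_id = character(0), cell_a = character(0),
               cell_b = character(0), distance = integer(0)),
      threshold = threshold
    ),
    class = "repertoire_network"
  )
}

#' @export
print.repertoire_network <- function(x, ...) {
  cat("CDR3 repertoire network (threshold ", x$threshold, ")\n", sep = "")
  cat("  patients: ", length(unique(x$nodes$patient_id)),
      ", cells: ", nrow(x$nodes), ", edges: ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Per-patient network statistics
#'
#' Number of connected components and maximum component size, raw and
#' normalized by the patient's cell count then log10-transformed (normalized
#' values are therefore <= 0).
#'
#' @param net A [build_network()] result.
#' @return Tibble per patient: `patient_id`, `n_cells`, `n_clusters_raw`,
#'   `max_cluster_size_raw`, `n_clusters_norm_log10`,
#'   `max_cluster_size_norm_log10`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "repertoire_network"))
  if (nrow(net$nodes) == 0) abort("network is empty; statistics are undefined.")
  net$nodes %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_cells = dplyr::n(),
      n_clusters_raw = dplyr::n_distinct(.data$component),
      max_cluster_size_raw = max(.data$component_size),
      .groups = "drop"
    ) %>%
    mutate(
      n_clusters_norm_log10 = log10(.data$n_clusters_raw / .data$n_cells),
      max_cluster_size_norm_log10 = log10(.data$max_cluster_size_raw / .data$n_cells)
    )
}

#' @method tidy repertoire_network
#' @export
tidy.repertoire_network <- function(x, ...) x$nodes

#' @method glance repertoire_network
#' @export
glance.repertoire_network <- function(x, ...) network_stats(x)
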