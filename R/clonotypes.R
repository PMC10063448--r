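#' Call per-sample clonotypes from paired gamma/delta sequences
#'
#' The clonotype key is the gamma full nucleotide sequence concatenated with
#' the delta full nucleotide sequence, scoped per sample: identical keys in
#' different samples are distinct clonotypes. Cells with an empty gamma or
#' delta sequence are dropped and listed in the audit attribute.
#'
#' @param paired Paired-cell tibble from [pair_cells()].
#' @return Cell-level tibble: `sample_id`, `barcode`, `vd_gene` (delta V
#'   call), `vd2_status` (`"Vd2pos"` if the delta V gene is TRDV2, else
#'   `"Vd2neg"`), `clonotype_key`, `delta_cdr3_aa`, `gamma_cdr3_aa`.
#' @export
call_clonotypes <- function(paired) {
  ok <- nzchar(paired$gamma_sequence_nt) & nzchar(paired$delta_sequence_nt)
  audit <- tibble(
    barcode = paired$barcode[!ok],
    reason = ifelse(!nzchar(paired$gamma_sequence_nt[!ok]),
                    "empty_gamma_sequence", "empty_delta_sequence")
  )
  cells <- paired[ok, , drop = FALSE] %>%
    mutate(
      vd_gene = .data$delta_v_gene,
      vd2_status = ifelse(.norm_gene(.data$delta_v_gene) == "TRDV2",
                          "Vd2pos", "Vd2neg"),
      clonotype_key = paste0(.data$gamma_sequence_nt, "+", .data$delta_sequence_nt)
    ) %>%
    select("sample_id", "barcode", "vd_gene", "vd2_status", "clonotype_key",
           delta_cdr3_aa = "delta_cdr3_aa", gamma_cdr3_aa = "gamma_cdr3_aa")
  attr(cells, "audit") <- audit
  cells
}

#' Label cells as expanded or singleton
#'
#' A cell is `"expanded"` when at least one other cell in the same sample
#' shares its clonotype key, `"singleton"` otherwise.
#'
#' @param cells Clonotype tibble from [call_clonotypes()].
#' @return The tibble with added `clone_size` and `expansion` columns.
#' @export
label_expansion <- function(cells) {
  cells %>%
    group_by(.data$sample_id, .data$clonotype_key) %>%
    mutate(clone_size = dplyr::n()) %>%
    ungroup() %>%
    mutate(expansion = ifelse(.data$clone_size >= 2L, "expanded", "singleton"))
}

#' Summarise expansion by group
#'
#' @param cells Labelled clonotype tibble ([label_expansion()]).
#' @param group_by Grouping column name, e.g. `"vd2_status"`, `"vd_gene"` or
#'   `"phenotype_cluster"`.
#' @return Tibble per group: `n_cells`, `n_expanded`, `pct_expanded`,
#'   `pct_singleton`. Empty groups are omitted.
#' @export
expansion_summary <- function(cells, group_by = "vd2_status") {
  if (!group_by %in% names(cells)) {
    abort(paste0("grouping column not found: ", group_by))
  }
  cells %>%
    filter(!is.na(.data[[group_by]])) %>%
    group_by(across(all_of(group_by))) %>%
    summarise(
      n_cells = dplyr::n(),
      n_expanded = sum(.data$expansion == "expanded"),
      .groups = "drop"
    ) %>%
    mutate(
      pct_expanded = 100 * .data$n_expanded / .data$n_cells,
      pct_singleton = 100 - .data$pct_expanded
    )
}

#' Per-sample clonotype size table
#'
#' @param cells Labelled clonotype tibble.
#' @return Tibble: `sample_id`, `clonotype_key`, `clone_size` (one row per
#'   clonotype).
#' @export
clonotype_sizes <- function(cells) {
  cells %>%
    count(.data$sample_id, .data$clonotype_key, name = "clone_size") %>%
    arrange(.data$sample_id, desc(.data$clone_size), .data$clonotype_key)
}

#' Delta-chain usage table
#'
#' Tabulates overall and within-Vdelta2-negative representation of each delta
#' V gene, computed from cell counts. The within-subset percentage equals the
#' overall percentage divided by the subset's overall fraction; this identity
#' holds to rounding because both derive from the same counts.
#'
#' @param cells Clonotype tibble with `vd_gene` and `vd2_status`.
#' @return Tibble per gene: `vd_gene`, `vd2_status`, `n`, `overall_pct`,
#'   `within_vd2neg_pct` (`NA` for Vdelta2-positive genes; all-`NA` when no
#'   Vdelta2-negative cells exist).
#' @export
chain_usage_table <- function(cells) {
  tab <- cells %>%
    count(.data$vd_gene, .data$vd2_status, name = "n") %>%
    mutate(overall_pct = 100 * .data$n / sum(.data$n))
  n_neg <- sum(tab$n[tab$vd2_status == "Vd2neg"])
  tab %>%
    mutate(
      within_vd2neg_pct = ifelse(
        .data$vd2_status == "Vd2neg" & n_neg > 0,
        100 * .data$n / n_neg, NA_real_
      )
    ) %>%
    arrange(desc(.data$n), .data$vd_gene)
}

#' Gini coefficient of a clone-size distribution
#'
#' Mean-absolute-difference form, `G = sum_ij |x_i - x_j| / (2 n^2 mu)`,
#' computed via the sorted identity; 0 for a perfectly even repertoire, and
#' strictly below 1. Scale-invariant and without small-sample correction.
#'
#' @param clone_sizes Non-empty vector of positive counts.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(clone_sizes) {
  x <- as.numeric(clone_sizes)
  if (length(x) == 0) abort("`clone_sizes` must be non-empty.")
  if (any(!is.finite(x)) || any(x <= 0)) abort("clone sizes must be positive.")
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
}

#' Compare paired Gini coefficients with the Wilcoxon signed-rank test
#'
#' Exact p-value for n <= 25 pairs without ties or zero differences, normal
#' approximation with continuity correction otherwise. Identical paired
#' vectors give p = 1.
#'
#' @param x,y Equal-length paired observations (e.g. per-patient Gini values
#'   under two conditions).
#' @return One-row tibble: `statistic` (V), `p_value`, `n`, `method`.
#' @export
compare_gini <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  d <- x - y
  if (all(d == 0)) {
    return(tibble(statistic = 0, p_value = 1, n = length(x),
                  method = "all differences zero"))
  }
  exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
  res <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         n = length(x), method = res$method)
}
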