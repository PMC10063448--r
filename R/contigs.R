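#' Productive-contig filter rules
#'
#' The six independently toggleable conditions defining a productive contig:
#' full-length span, initiator codon at the expected position, CDR3 detected,
#' in-frame junction, no internal stop codon, and V/J calls from a consistent
#' locus. When a record already carries a definite `productive` flag the flag
#' is trusted by default (`trust_flag = TRUE`); records with an unknown flag
#' are always evaluated against the rules.
#'
#' @param require_full_length,require_start_codon,require_cdr3,
#'   require_in_frame,forbid_internal_stop,require_consistent_locus Logical
#'   toggles, all `TRUE` by default.
#' @param trust_flag Use a definite upstream `productive` flag verbatim
#'   instead of re-evaluating the rules for that record.
#' @return A `productive_rules` list.
#' @export
productive_rules <- function(require_full_length = TRUE,
                             require_start_codon = TRUE,
                             require_cdr3 = TRUE,
                             require_in_frame = TRUE,
                             forbid_internal_stop = TRUE,
                             require_consistent_locus = TRUE,
                             trust_flag = TRUE) {
  structure(
    list(
      require_full_length = require_full_length,
      require_start_codon = require_start_codon,
      require_cdr3 = require_cdr3,
      require_in_frame = require_in_frame,
      forbid_internal_stop = forbid_internal_stop,
      require_consistent_locus = require_consistent_locus,
      trust_flag = trust_flag
    ),
    class = "productive_rules"
  )
}

.gene_locus <- function(gene) {
  g <- toupper(gene)
  loc <- substr(g, 1, 3)
  # hybrid TRAV..DV segments rearrange at either locus
  hybrid <- .is_hybrid_v(g)
  ifelse(hybrid, "TRA|TRD", ifelse(nzchar(g), loc, ""))
}

.locus_consistent <- function(v_gene, j_gene) {
  lv <- .gene_locus(v_gene)
  lj <- .gene_locus(j_gene)
  mapply(function(a, b) {
    if (!nzchar(a) || !nzchar(b)) return(TRUE)  # incompleteness caught elsewhere
    length(intersect(strsplit(a, "|", fixed = TRUE)[[1]],
                     strsplit(b, "|", fixed = TRUE)[[1]])) > 0
  }, lv, lj, USE.NAMES = FALSE)
}

#' Filter a contig table to productive contigs
#'
#' Applies [productive_rules()] and keeps only records passing every enabled
#' condition. Records excluded are recorded, with one reason code per failed
#' condition, in an audit table retrievable with [productive_audit()].
#'
#' @param contigs Normalized contig tibble (see [read_contigs()]).
#' @param rules A [productive_rules()] object.
#' @return The surviving rows, with the audit tibble attached as the
#'   `"audit"` attribute.
#' @export
filter_productive <- function(contigs, rules = productive_rules()) {
  stopifnot(inherits(rules, "productive_rules"))
  n <- nrow(contigs)
  if (n == 0) {
    out <- contigs
    attr(out, "audit") <- tibble(contig_id = character(0), reason = character(0))
    return(out)
  }
  fails <- list()
  add_fail <- function(bad, reason) {
    if (any(bad)) {
      fails[[length(fails) + 1]] <<- tibble(
        contig_id = contigs$contig_id[bad], reason = reason
      )
    }
    bad
  }
  bad_any <- rep(FALSE, n)
  flag_known <- rules$trust_flag & !is.na(contigs$productive)
  eval_rules <- !flag_known

  bad_any <- bad_any | add_fail(flag_known & !contigs$productive, "flag_unproductive")

  if (rules$require_full_length) {
    bad <- eval_rules & (is.na(contigs$full_length) | !contigs$full_length)
    bad_any <- bad_any | add_fail(bad, "not_full_length")
  }
  if (rules$require_start_codon) {
    bad <- eval_rules & nzchar(contigs$sequence_nt) &
      substr(contigs$sequence_nt, 1, 3) != "ATG"
    bad_any <- bad_any | add_fail(bad, "no_start_codon")
  }
  if (rules$require_cdr3) {
    bad <- eval_rules & !nzchar(contigs$cdr3_nt) & !nzchar(contigs$cdr3_aa)
    bad_any <- bad_any | add_fail(bad, "no_cdr3")
  }
  if (rules$require_in_frame) {
    bad <- eval_rules & nzchar(contigs$cdr3_nt) & nchar(contigs$cdr3_nt) %% 3 != 0
    bad_any <- bad_any | add_fail(bad, "out_of_frame")
  }
  if (rules$forbid_internal_stop) {
    aa <- ifelse(nzchar(contigs$cdr3_aa), contigs$cdr3_aa,
                 ifelse(nzchar(contigs$cdr3_nt) & nchar(contigs$cdr3_nt) %% 3 == 0,
                        translate_nt(contigs$cdr3_nt), ""))
    bad <- eval_rules & grepl("*", aa, fixed = TRUE)
    bad_any <- bad_any | add_fail(bad, "internal_stop")
  }
  if (rules$require_consistent_locus) {
    bad <- eval_rules & !.locus_consistent(contigs$v_gene, contigs$j_gene)
    bad_any <- bad_any | add_fail(bad, "inconsistent_locus")
  }
  out <- contigs[!bad_any, , drop = FALSE]
  attr(out, "audit") <- if (length(fails)) {
    bind_rows(fails) %>% arrange(.data$contig_id, .data$reason)
  } else {
    tibble(contig_id = character(0), reason = character(0))
  }
  out
}

#' Retrieve the exclusion audit of a filtered table
#' @param x Result of [filter_productive()] or [call_clonotypes()].
#' @return Tibble of excluded record ids and reason codes.
#' @export
productive_audit <- function(x) {
  attr(x, "audit") %||% tibble(contig_id = character(0), reason = character(0))
}

.default_hybrid_genes <- c(
  "TRAV14DV4", "TRAV23DV6", "TRAV29DV5", "TRAV36DV7", "TRAV38-2DV8"
)

.norm_gene <- function(x) gsub("/", "", toupper(x), fixed = TRUE)

#' Reassign hybrid TRAV/DV contigs to the delta locus
#'
#' Hybrid V segments such as TRAV29DV5 rearrange in both alpha and delta
#' chains; a contig using one is a true delta chain only when its D, J and C
#' calls are all delta-locus genes. Such contigs have `chain` set to `"TRD"`;
#' every other field, and every other record, is left untouched. Matching is
#' case-insensitive and tolerates the `TRAV14/DV4` spelling.
#'
#' @param contigs Normalized contig tibble.
#' @param hybrid_genes Character set of hybrid V genes.
#' @return The contig tibble with updated `chain`.
#' @export
reassign_hybrid_delta <- function(contigs, hybrid_genes = .default_hybrid_genes) {
  if (nrow(contigs) == 0) return(contigs)
  hyb <- .norm_gene(contigs$v_gene) %in% .norm_gene(hybrid_genes)
  all_delta <- startsWith(toupper(contigs$d_gene), "TRD") &
    startsWith(toupper(contigs$j_gene), "TRD") &
    startsWith(toupper(contigs$c_gene), "TRD")
  contigs$chain[hyb & all_delta] <- "TRD"
  contigs
}

#' Keep one contig per cell and locus
#'
#' Restricts to TRG/TRD records and resolves cells carrying more than one
#' contig for a locus: the highest-UMI contig wins, ties broken by read count
#' and then lexicographically smallest `contig_id`, so the result is
#' deterministic regardless of input row order.
#'
#' @param contigs Productive, delta-reassigned contig tibble.
#' @return Contig tibble with at most one TRG and one TRD row per
#'   (sample, barcode).
#' @export
select_cell_chains <- function(contigs) {
  contigs %>%
    filter(.data$chain %in% c("TRG", "TRD")) %>%
    group_by(.data$sample_id, .data$barcode, .data$chain) %>%
    arrange(desc(.data$umis), desc(.data$reads), .data$contig_id, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$barcode, .data$chain)
}

#' Pair gamma and delta chains by cell barcode
#'
#' Inner-joins the TRG and TRD records of each (sample, barcode). Cells with
#' only one chain are reported in the `"orphans"` attribute (retrievable with
#' [orphan_cells()]), not in the paired table.
#'
#' @param contigs One-chain-per-locus contig tibble (see
#'   [select_cell_chains()]).
#' @return Tibble with one row per paired cell: `sample_id`, `barcode`, and
#'   every contig field prefixed `gamma_` / `delta_`.
#' @export
pair_cells <- function(contigs) {
  pref <- function(df, p) {
    keep <- setdiff(names(df), c("sample_id", "barcode", "chain"))
    df <- df[c("sample_id", "barcode", keep)]
    names(df)[-(1:2)] <- paste0(p, keep)
    df
  }
  g <- pref(filter(contigs, .data$chain == "TRG"), "gamma_")
  d <- pref(filter(contigs, .data$chain == "TRD"), "delta_")
  paired <- inner_join(g, d, by = c("sample_id", "barcode")) %>%
    arrange(.data$sample_id, .data$barcode)
  orphans <- bind_rows(
    anti_join(g, d, by = c("sample_id", "barcode")) %>%
      select("sample_id", "barcode") %>% mutate(missing_chain = "TRD"),
    anti_join(d, g, by = c("sample_id", "barcode")) %>%
      select("sample_id", "barcode") %>% mutate(missing_chain = "TRG")
  ) %>% arrange(.data$sample_id, .data$barcode)
  attr(paired, "orphans") <- orphans
  paired
}

#' Retrieve orphan-chain cells from a paired table
#' @param paired Result of [pair_cells()].
#' @return Tibble of cells lacking one chain, with the missing locus.
#' @export
orphan_cells <- function(paired) {
  attr(paired, "orphans") %||%
    tibble(sample_id = character(0), barcode = character(0),
           missing_chain = character(0))
}
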