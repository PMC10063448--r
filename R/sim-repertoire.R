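#' Configure a synthetic paired gamma/delta repertoire
#'
#' Builds the configuration object consumed by [simulate_repertoire()]. The
#' generator plants a known clone structure: each clone receives one gamma and
#' one delta nucleotide sequence, copied verbatim to every member cell, so
#' clonotype identity downstream is guaranteed by construction.
#'
#' @param n_cells Number of cells to simulate. Ignored (derived) when
#'   `clone_sizes` is supplied.
#' @param clone_sizes Optional explicit integer vector of clone sizes; its sum
#'   defines the number of cells. When `NULL`, clone sizes are drawn from a
#'   discrete power law with exponent `power_law_exponent` on
#'   `1:max_clone_size` until `n_cells` cells are filled (the last clone is
#'   truncated to fit).
#' @param power_law_exponent Exponent of the clone-size power law (default
#'   2.5, a typical repertoire tail).
#' @param max_clone_size Support upper bound for the power law.
#' @param chain_usage Named numeric vector mapping delta V genes to clone
#'   proportions; must sum to 1. Defaults reflect a tumour-infiltrating
#'   gamma delta repertoire dominated by Vdelta1 with a substantial Vdelta2
#'   and hybrid TRAV/DV component.
#' @param gamma_gene_pool Gamma V genes sampled uniformly per clone.
#' @param frac_unproductive Per-contig probability of being emitted as
#'   unproductive (internal stop codon planted in the CDR3, productive flag
#'   FALSE).
#' @param frac_orphan_gamma,frac_orphan_delta Fractions of cells emitted with
#'   only a gamma (respectively only a delta) contig.
#' @param cdr3_length_range Integer pair: CDR3 amino-acid length bounds.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A `repertoire_sim_config` list.
#' @export
repertoire_sim_config <- function(n_cells = 1000,
                                  clone_sizes = NULL,
                                  power_law_exponent = 2.5,
                                  max_clone_size = 30,
                                  chain_usage = c(
                                    TRDV1 = 0.36, TRDV2 = 0.28,
                                    TRAV14DV4 = 0.13, TRAV29DV5 = 0.07,
                                    TRAV23DV6 = 0.07, TRDV3 = 0.06,
                                    TRAV36DV7 = 0.03
                                  ),
                                  gamma_gene_pool = c(
                                    "TRGV2", "TRGV3", "TRGV4", "TRGV5",
                                    "TRGV8", "TRGV9", "TRGV10"
                                  ),
                                  frac_unproductive = 0,
                                  frac_orphan_gamma = 0,
                                  frac_orphan_delta = 0,
                                  cdr3_length_range = c(8L, 20L),
                                  seed = 1L) {
  if (!is.null(clone_sizes)) {
    clone_sizes <- as.integer(clone_sizes)
    if (any(clone_sizes < 1)) abort("`clone_sizes` must be positive integers.")
    n_cells <- sum(clone_sizes)
  }
  if (abs(sum(chain_usage) - 1) > 1e-9) {
    abort("`chain_usage` proportions must sum to 1.")
  }
  if (is.null(names(chain_usage)) || any(!nzchar(names(chain_usage)))) {
    abort("`chain_usage` must be a named vector of delta V genes.")
  }
  for (f in c(frac_unproductive, frac_orphan_gamma, frac_orphan_delta)) {
    if (f < 0 || f > 1) abort("noise fractions must lie in [0, 1].")
  }
  if (length(cdr3_length_range) != 2 || cdr3_length_range[1] > cdr3_length_range[2] ||
      cdr3_length_range[1] < 1) {
    abort("`cdr3_length_range` must be an increasing positive integer pair.")
  }
  structure(
    list(
      n_cells = as.integer(n_cells), clone_sizes = clone_sizes,
      power_law_exponent = power_law_exponent,
      max_clone_size = as.integer(max_clone_size),
      chain_usage = chain_usage, gamma_gene_pool = gamma_gene_pool,
      frac_unproductive = frac_unproductive,
      frac_orphan_gamma = frac_orphan_gamma,
      frac_orphan_delta = frac_orphan_delta,
      cdr3_length_range = as.integer(cdr3_length_range),
      seed = as.integer(seed)
    ),
    class = "repertoire_sim_config"
  )
}

# codons that never translate to a stop
.sense_codons <- local({
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
})

.random_codons <- function(n) paste(sample(.sense_codons, n, replace = TRUE), collapse = "")

#' Translate nucleotide sequences to amino acids
#'
#' Standard-table translation; internal stops appear as `*`.
#' @param nt Character vector of nucleotide sequences (length divisible by 3).
#' @return Character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  out <- rep("", length(nt))
  ok <- nzchar(nt)
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]),
      no.init.codon = TRUE
    ))
  }
  out
}

.draw_clone_sizes <- function(cfg) {
  if (!is.null(cfg$clone_sizes)) return(cfg$clone_sizes)
  support <- seq_len(cfg$max_clone_size)
  p <- support^(-cfg$power_law_exponent)
  p <- p / sum(p)
  sizes <- integer(0)
  total <- 0L
  while (total < cfg$n_cells) {
    s <- sample(support, 1L, prob = p)
    s <- min(s, cfg$n_cells - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes
}

# One in-frame receptor sequence: ATG leader, V region, CDR3 opening with the
# canonical cysteine codon, J/C tail. No internal stops unless planted later.
.make_chain_seq <- function(cdr3_len) {
  cdr3_nt <- paste0("TGT", .random_codons(cdr3_len - 1L))
  seq_nt <- paste0("ATG", .random_codons(40L), cdr3_nt, .random_codons(20L))
  list(cdr3_nt = cdr3_nt, sequence_nt = seq_nt)
}

.is_hybrid_v <- function(gene) {
  grepl("^TRAV[0-9]", toupper(gene)) & grepl("DV[0-9]", toupper(gene))
}

#' Simulate a paired gamma/delta contig table with planted ground truth
#'
#' Emits one gamma and one delta contig per intact cell (shared barcode);
#' clone members share identical gamma and delta nucleotide sequences. Hybrid
#' TRAV/DV delta chains are emitted with the `TRA` chain call and delta
#' D/J/C genes, as annotation pipelines produce them, so the delta
#' reassignment step is exercised. Noise (unproductive contigs, orphan-chain
#' cells) is injected at the configured rates.
#'
#' @param config A [repertoire_sim_config()].
#' @param sample_id Sample label written on every record.
#' @return A list with `contigs` (normalized contig tibble) and `truth`
#'   (per-cell tibble: clone id/size, genes, sequences, productivity and
#'   orphan flags).
#' @export
simulate_repertoire <- function(config, sample_id = "S1") {
  stopifnot(inherits(config, "repertoire_sim_config"))
  with_seed(config$seed, {
    sizes <- .draw_clone_sizes(config)
    n_clones <- length(sizes)
    vd_genes <- sample(names(config$chain_usage), n_clones,
                       replace = TRUE, prob = config$chain_usage)
    g_genes <- sample(config$gamma_gene_pool, n_clones, replace = TRUE)
    lens <- sample(seq(config$cdr3_length_range[1], config$cdr3_length_range[2]),
                   2L * n_clones, replace = TRUE)
    gamma_seqs <- lapply(lens[seq_len(n_clones)], .make_chain_seq)
    delta_seqs <- lapply(lens[n_clones + seq_len(n_clones)], .make_chain_seq)

    truth <- tibble(
      clone_id = rep(seq_len(n_clones), sizes),
      clone_size = rep(sizes, sizes),
      vd_gene = rep(vd_genes, sizes),
      gamma_gene = rep(g_genes, sizes)
    )
    n <- nrow(truth)
    truth$sample_id <- sample_id
    truth$barcode <- sprintf("BC%05d-1", seq_len(n))
    truth$gamma_nt <- vapply(gamma_seqs, `[[`, "", "sequence_nt")[truth$clone_id]
    truth$gamma_cdr3_nt <- vapply(gamma_seqs, `[[`, "", "cdr3_nt")[truth$clone_id]
    truth$delta_nt <- vapply(delta_seqs, `[[`, "", "sequence_nt")[truth$clone_id]
    truth$delta_cdr3_nt <- vapply(delta_seqs, `[[`, "", "cdr3_nt")[truth$clone_id]

    # per-contig unproductive noise: plant a stop codon inside the CDR3
    truth$gamma_productive <- runif(n) >= config$frac_unproductive
    truth$delta_productive <- runif(n) >= config$frac_unproductive
    plant_stop <- function(cdr3) {
      pos <- 3L * sample(seq(2L, nchar(cdr3) / 3L - 1L), 1L) - 2L
      paste0(substr(cdr3, 1L, pos - 1L), "TAA", substr(cdr3, pos + 3L, nchar(cdr3)))
    }
    for (i in which(!truth$gamma_productive)) {
      bad <- plant_stop(truth$gamma_cdr3_nt[i])
      truth$gamma_nt[i] <- sub(truth$gamma_cdr3_nt[i], bad, truth$gamma_nt[i], fixed = TRUE)
      truth$gamma_cdr3_nt[i] <- bad
    }
    for (i in which(!truth$delta_productive)) {
      bad <- plant_stop(truth$delta_cdr3_nt[i])
      truth$delta_nt[i] <- sub(truth$delta_cdr3_nt[i], bad, truth$delta_nt[i], fixed = TRUE)
      truth$delta_cdr3_nt[i] <- bad
    }
    truth$gamma_cdr3_aa <- translate_nt(truth$gamma_cdr3_nt)
    truth$delta_cdr3_aa <- translate_nt(truth$delta_cdr3_nt)

    # orphan cells: drop the other chain
    truth$has_gamma <- TRUE
    truth$has_delta <- TRUE
    n_og <- round(config$frac_orphan_gamma * n)
    n_od <- round(config$frac_orphan_delta * n)
    pick <- sample(n, min(n, n_og + n_od))
    truth$has_delta[pick[seq_len(n_og)]] <- FALSE
    truth$has_gamma[pick[n_og + seq_len(n_od)]] <- FALSE

    gamma <- truth %>%
      filter(.data$has_gamma) %>%
      mutate(
        contig_id = paste0(.data$barcode, "_contig_1"),
        chain = "TRG", v_gene = .data$gamma_gene, d_gene = "",
        j_gene = "TRGJ1", c_gene = "TRGC1",
        full_length = TRUE, productive = .data$gamma_productive,
        cdr3_aa = .data$gamma_cdr3_aa, cdr3_nt = .data$gamma_cdr3_nt,
        sequence_nt = .data$gamma_nt
      )
    delta <- truth %>%
      filter(.data$has_delta) %>%
      mutate(
        contig_id = paste0(.data$barcode, "_contig_2"),
        chain = ifelse(.is_hybrid_v(.data$vd_gene), "TRA", "TRD"),
        v_gene = .data$vd_gene, d_gene = "TRDD3",
        j_gene = "TRDJ1", c_gene = "TRDC",
        full_length = TRUE, productive = .data$delta_productive,
        cdr3_aa = .data$delta_cdr3_aa, cdr3_nt = .data$delta_cdr3_nt,
        sequence_nt = .data$delta_nt
      )
    cols <- c("sample_id", "barcode", "contig_id", "chain", "v_gene", "d_gene",
              "j_gene", "c_gene", "full_length", "productive", "cdr3_aa",
              "cdr3_nt", "sequence_nt")
    contigs <- bind_rows(gamma[cols], delta[cols]) %>%
      mutate(
        umis = 1L + rnbinom(dplyr::n(), mu = 6, size = 2),
        reads = .data$umis * (10L + rnbinom(dplyr::n(), mu = 40, size = 2))
      ) %>%
      arrange(.data$barcode, .data$contig_id)
    list(contigs = contigs, truth = truth)
  })
}
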