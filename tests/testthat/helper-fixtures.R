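# Programmatic fixtures: a contig-record builder with sensible defaults,
# overridable per field.
make_contig <- function(...) {
  defaults <- list(
    sample_id = "S1", barcode = "BC1", contig_id = "BC1_contig_1",
    chain = "TRD", v_gene = "TRDV1", d_gene = "TRDD3", j_gene = "TRDJ1",
    c_gene = "TRDC", full_length = TRUE, productive = NA,
    cdr3_aa = "CALGDT", cdr3_nt = "TGTGCTCTGGGTGATACT",
    sequence_nt = paste0("ATG", strrep("GCA", 40), "TGTGCTCTGGGTGATACT",
                         strrep("GGT", 20)),
    umis = 5L, reads = 100L
  )
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

make_contigs <- function(...) dplyr::bind_rows(...)

# A minimal gdx with fully controlled counts.
make_gdx <- function(counts, ...) {
  gdtcr::gdx(counts, ...)
}

# Paired-cell rows as produced by pair_cells(), built directly for clonotype
# unit tests.
make_paired <- function(sample_id, barcode, gamma_nt, delta_nt,
                        delta_v = "TRDV1", delta_cdr3_aa = "CALGDT") {
  tibble::tibble(
    sample_id = sample_id, barcode = barcode,
    gamma_contig_id = paste0(barcode, "_g"),
    gamma_v_gene = "TRGV9", gamma_d_gene = "", gamma_j_gene = "TRGJ1",
    gamma_c_gene = "TRGC1", gamma_full_length = TRUE, gamma_productive = TRUE,
    gamma_cdr3_aa = "CATWDG", gamma_cdr3_nt = "TGTGCAACATGGGATGGT",
    gamma_sequence_nt = gamma_nt, gamma_umis = 3L, gamma_reads = 50L,
    delta_contig_id = paste0(barcode, "_d"),
    delta_v_gene = delta_v, delta_d_gene = "TRDD3", delta_j_gene = "TRDJ1",
    delta_c_gene = "TRDC", delta_full_length = TRUE, delta_productive = TRUE,
    delta_cdr3_aa = delta_cdr3_aa, delta_cdr3_nt = "TGTGCTCTGGGTGATACT",
    delta_sequence_nt = delta_nt, delta_umis = 4L, delta_reads = 60L
  )
}
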