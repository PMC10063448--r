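test_that("the 10x reader normalizes fields and truth strings", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,contig_id,chain,v_gene,d_gene,j_gene,c_gene,full_length,productive,cdr3,cdr3_nt,umis,reads",
    "BC1,BC1_c1,TRD,TRDV1,TRDD3,TRDJ1,TRDC,True,True,CALGDT,TGTGCTCTGGGTGATACT,5,80",
    "BC2,BC2_c1,TRG,TRGV9,,TRGJ1,TRGC1,true,False,CATWDG,TGTGCAACATGGGATGGT,3,40",
    "BC3,BC3_c1,TRA,TRAV29DV5,None,TRAJ12,TRAC,T,None,CAVR,TGTGCTGTGAGA,2,20"
  ), f)
  tab <- read_contigs(f, "tenx_csv")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$productive, c(TRUE, FALSE, NA))
  expect_equal(tab$full_length, c(TRUE, TRUE, TRUE))
  expect_equal(tab$d_gene, c("TRDD3", "", ""))
  expect_equal(tab$chain, c("TRD", "TRG", "TRA"))
})

test_that("the AIRR reader maps locus and junction columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cell_id", "sequence_id", "locus", "v_call", "j_call", "productive",
          "junction", "junction_aa", "duplicate_count", sep = "\t"),
    paste("BC1", "seq1", "TRD", "TRDV2", "TRDJ1", "T",
          "TGTGCTCTGGGTGATACT", "CALGDT", "7", sep = "\t")
  ), f)
  tab <- read_contigs(f, "airr_tsv")
  expect_equal(tab$chain, "TRD")
  expect_equal(tab$cdr3_aa, "CALGDT")
  expect_equal(tab$umis, 7L)
})

test_that("missing mandatory columns are reported by name", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("barcode,chain", "BC1,TRD"), f)
  expect_error(read_contigs(f, "tenx_csv"), "contig_id")
})

test_that("productive filtering excludes known violations with reasons", {
  good <- function(i) make_contig(barcode = paste0("BC", i),
                                  contig_id = paste0("BC", i, "_c"))
  fixture <- make_contigs(
    good(1), good(2), good(3), good(4), good(5), good(6),
    make_contig(barcode = "BC7", contig_id = "BC7_c", full_length = FALSE),
    make_contig(barcode = "BC8", contig_id = "BC8_c",
                sequence_nt = paste0("GTG", strrep("GCA", 20))),
    make_contig(barcode = "BC9", contig_id = "BC9_c", cdr3_aa = "", cdr3_nt = ""),
    make_contig(barcode = "BC10", contig_id = "BC10_c",
                cdr3_aa = "CAL*DT", cdr3_nt = "TGTGCTCTGTAAGATACT")
  )
  out <- filter_productive(fixture)
  expect_equal(nrow(out), 6)
  audit <- productive_audit(out)
  expect_equal(nrow(audit), 4)
  expect_setequal(audit$reason, c("not_full_length", "no_start_codon",
                                  "no_cdr3", "internal_stop"))
})

test_that("a definite productive flag short-circuits rule evaluation", {
  rec <- make_contig(productive = TRUE, full_length = FALSE)
  expect_equal(nrow(filter_productive(rec)), 1)
  expect_equal(nrow(filter_productive(rec, productive_rules(trust_flag = FALSE))), 0)
  rec2 <- make_contig(productive = FALSE)
  expect_equal(nrow(filter_productive(rec2)), 0)
  expect_equal(productive_audit(filter_productive(rec2))$reason, "flag_unproductive")
})

test_that("in-frame and locus-consistency rules catch the remaining violations", {
  out_of_frame <- make_contig(cdr3_nt = "TGTGCTCTGG", cdr3_aa = "")
  expect_equal(productive_audit(filter_productive(out_of_frame))$reason, "out_of_frame")
  crossed <- make_contig(v_gene = "TRDV1", j_gene = "TRGJ1")
  expect_equal(productive_audit(filter_productive(crossed))$reason,
               "inconsistent_locus")
  # hybrid V segments are consistent with both TRA and TRD J genes
  hybrid <- make_contig(v_gene = "TRAV29DV5", j_gene = "TRDJ1", chain = "TRA")
  expect_equal(nrow(filter_productive(hybrid)), 1)
})

test_that("filter_productive is idempotent and order-insensitive", {
  sim <- simulate_repertoire(repertoire_sim_config(
    n_cells = 60, frac_unproductive = 0.3, seed = 8
  ))
  tab <- sim$contigs
  tab$productive <- NA  # force rule evaluation
  once <- filter_productive(tab)
  twice <- filter_productive(once)
  strip <- function(x) { attr(x, "audit") <- NULL; as.data.frame(x) }
  expect_equal(strip(once), strip(twice))
  expect_equal(nrow(productive_audit(twice)), 0)
  shuffled <- filter_productive(tab[sample(nrow(tab)), ])
  expect_setequal(once$contig_id, shuffled$contig_id)
})

test_that("hybrid TRAV/DV contigs move to TRD only when D, J and C are delta", {
  hits <- make_contig(chain = "TRA", v_gene = "TRAV29DV5",
                      d_gene = "TRDD3", j_gene = "TRDJ1", c_gene = "TRDC")
  expect_equal(reassign_hybrid_delta(hits)$chain, "TRD")
  already <- make_contig(chain = "TRD", v_gene = "TRDV1")
  expect_equal(reassign_hybrid_delta(already)$chain, "TRD")
  alpha <- make_contig(chain = "TRA", v_gene = "TRAV29DV5",
                       d_gene = "", j_gene = "TRAJ12", c_gene = "TRAC")
  expect_equal(reassign_hybrid_delta(alpha)$chain, "TRA")
  # spelling and case tolerance
  slash <- make_contig(chain = "TRA", v_gene = "trav14/dv4",
                       d_gene = "TRDD3", j_gene = "TRDJ1", c_gene = "TRDC")
  expect_equal(reassign_hybrid_delta(slash)$chain, "TRD")
})

test_that("reassignment changes only the chain field", {
  tab <- make_contigs(
    make_contig(chain = "TRA", v_gene = "TRAV29DV5",
                d_gene = "TRDD3", j_gene = "TRDJ1", c_gene = "TRDC"),
    make_contig(barcode = "BC2", contig_id = "BC2_c")
  )
  out <- reassign_hybrid_delta(tab)
  expect_equal(out[setdiff(names(out), "chain")],
               tab[setdiff(names(tab), "chain")])
})

test_that("chain selection keeps the UMI-max contig with deterministic ties", {
  two <- make_contigs(
    make_contig(contig_id = "BC1_a", umis = 5L),
    make_contig(contig_id = "BC1_b", umis = 2L)
  )
  expect_equal(select_cell_chains(two)$contig_id, "BC1_a")
  tie <- make_contigs(
    make_contig(contig_id = "BC1_z", umis = 5L, reads = 100L),
    make_contig(contig_id = "BC1_a", umis = 5L, reads = 100L)
  )
  expect_equal(select_cell_chains(tie)$contig_id, "BC1_a")
  expect_equal(select_cell_chains(tie[2:1, ])$contig_id, "BC1_a")
})

test_that("pairing joins on barcode and reports orphans", {
  tab <- make_contigs(
    make_contig(barcode = "BC1", chain = "TRG", v_gene = "TRGV9",
                j_gene = "TRGJ1", c_gene = "TRGC1", contig_id = "BC1_g"),
    make_contig(barcode = "BC1", contig_id = "BC1_d"),
    make_contig(barcode = "BC2", chain = "TRG", v_gene = "TRGV9",
                j_gene = "TRGJ1", c_gene = "TRGC1", contig_id = "BC2_g")
  )
  paired <- pair_cells(tab)
  expect_equal(nrow(paired), 1)
  expect_equal(paired$barcode, "BC1")
  orph <- orphan_cells(paired)
  expect_equal(orph$barcode, "BC2")
  expect_equal(orph$missing_chain, "TRD")
  # empty delta set
  gamma_only <- tab[c(1, 3), ]
  expect_equal(nrow(pair_cells(gamma_only)), 0)
})

test_that("zero-noise simulation pairs every cell", {
  sim <- simulate_repertoire(repertoire_sim_config(n_cells = 50, seed = 14))
  paired <- sim$contigs %>%
    filter_productive() %>%
    reassign_hybrid_delta() %>%
    select_cell_chains() %>%
    pair_cells()
  expect_equal(nrow(paired), 50)
  expect_equal(nrow(orphan_cells(paired)), 0)
})
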