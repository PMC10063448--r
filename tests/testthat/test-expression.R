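base_counts <- function(n_genes = 30, n_cells = 10, value = 1) {
  m <- matrix(value, n_genes, n_cells,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("C%02d", seq_len(n_cells))))
  m
}

test_that("QC applies its stages in order with strict upper bounds", {
  # 300 ubiquitous genes so every gene survives the >=3-cells rule
  m <- base_counts(300, 6)
  rownames(m)[1] <- "MT-1"
  m["G003", 1] <- 19701            # cell C01: 299 + 19701 = exactly 20000 counts
  stopifnot(sum(m[, 1]) == 20000)
  m["MT-1", 2] <- 33               # cell C02: mito 33, other 297
  m[c("G299", "G300"), 2] <- 0     #   -> 33/330 = exactly 10% mito
  m[, 4] <- 0                      # cell C04: only 150 genes detected
  m[1:150, 4] <- 1
  rare <- rbind(m, RARE = 0)       # a gene seen in only 2 cells
  rare["RARE", c(3, 5)] <- 5
  x <- qc_filter(gdx(rare))
  expect_false("RARE" %in% rownames(x$counts))
  expect_false("C01" %in% colnames(x$counts))  # 20000 counts not < 20000
  expect_false("C02" %in% colnames(x$counts))  # 10% mito not < 10%
  expect_false("C04" %in% colnames(x$counts))  # 150 genes < 200
  expect_setequal(colnames(x$counts), c("C03", "C05", "C06"))
  audit <- attr(x, "qc_audit")
  expect_equal(audit$cells_below_min_genes, 1)
  expect_equal(audit$genes_below_min_cells, 1)
  expect_equal(audit$cells_above_upper_bounds, 2)
})

test_that("QC failure modes raise stage-attributed errors", {
  m <- base_counts(50, 4)  # 50 genes < 200 floor for every cell
  expect_error(qc_filter(gdx(m)), "min-genes")
})

test_that("normalization scales to the target sum before log1p", {
  m <- matrix(c(10, 90), 2, 1, dimnames = list(c("A", "B"), "C1"))
  x <- normalize_log(gdx(m))
  expect_equal(as.numeric(x$logcounts), log1p(c(1000, 9000)))
  # identical cells map to identical vectors
  m2 <- base_counts(10, 3, value = 2)
  x2 <- normalize_log(gdx(m2))
  expect_equal(x2$logcounts[, 1], x2$logcounts[, 2])
  # round trip: expm1 row sums return the target
  es <- simulate_expression(expression_sim_config(n_cells = 50, n_genes = 100, seed = 2))
  x3 <- normalize_log(qc_filter(gdx(es$counts), qc_thresholds(min_genes = 10)))
  expect_equal(max(abs(Matrix::colSums(expm1(x3$logcounts)) - 1e4)), 0,
               tolerance = 1e-6)
})

test_that("batch adjustment removes an additive shift and is null-safe", {
  es <- simulate_expression(expression_sim_config(
    n_cells = 100, n_genes = 120, n_clusters = 1, vd_marker_genes = c(),
    signature_effect = 0, seed = 9
  ))
  x <- normalize_log(qc_filter(gdx(es$counts, cell_meta = es$cell_meta),
                               qc_thresholds(min_genes = 10)))
  batch <- rep(c("B1", "B2"), length.out = ncol(x$counts))
  x$cells$batch <- batch
  shifted <- x
  shifted$logcounts <- as.matrix(shifted$logcounts)
  shifted$logcounts[, batch == "B2"] <- shifted$logcounts[, batch == "B2"] + 0.7
  adj <- batch_adjust(shifted)
  mu1 <- rowMeans(adj$logcounts[, batch == "B1"])
  mu2 <- rowMeans(adj$logcounts[, batch == "B2"])
  expect_equal(mu1, mu2, tolerance = 1e-9)
  # batch-free data: adjustment only removes sampling noise in batch means
  bal <- batch_adjust(x)
  expect_lt(mean(abs(as.matrix(bal$logcounts) - as.matrix(x$logcounts))), 0.2)
  # single batch: identity with a warning
  x$cells$batch <- "B1"
  expect_warning(same <- batch_adjust(x), "single batch")
  expect_equal(same$logcounts, x$logcounts)
})

test_that("batch adjustment preserves a planted biological contrast", {
  es <- simulate_expression(expression_sim_config(
    n_cells = 200, n_genes = 150, n_clusters = 2, vd_marker_genes = c(),
    signature_effect = 1.5, batch_labels = 2, batch_effect_sd = 0.8, seed = 12
  ))
  x <- normalize_log(qc_filter(gdx(es$counts, cell_meta = es$cell_meta),
                               qc_thresholds(min_genes = 10)))
  adj <- batch_adjust(x)
  sig <- intersect(paste0("SIG", 1:25), rownames(adj$logcounts))
  g1 <- adj$cells$true_cluster == 1
  contrast <- mean(adj$logcounts[sig, g1]) - mean(adj$logcounts[sig, !g1])
  expect_gt(contrast, 0.3)
})

test_that("clustering recovers planted groups, deterministically", {
  es <- simulate_expression(expression_sim_config(
    n_cells = 300, n_genes = 400, n_clusters = 2, seed = 5
  ))
  x <- cluster_cells(normalize_log(qc_filter(gdx(es$counts, cell_meta = es$cell_meta))),
                     seed = 1)
  expect_gt(ari(x$cells$leiden_cluster, x$cells$true_cluster), 0.9)
  x2 <- cluster_cells(normalize_log(qc_filter(gdx(es$counts))), seed = 1)
  expect_identical(x$cells$leiden_cluster, x2$cells$leiden_cluster)
  # identical cells collapse to one cluster
  flat <- normalize_log(gdx(base_counts(20, 30, value = 3)))
  flat_cl <- cluster_cells(flat, n_neighbors = 5)
  expect_equal(unique(flat_cl$cells$leiden_cluster), 1L)
  expect_error(cluster_cells(flat, n_neighbors = 50), "n_neighbors")
})

test_that("Vdelta2 labels follow the argmax rule with ties unassigned", {
  m <- base_counts(10, 4, value = 1)
  rownames(m)[1:3] <- c("TRDV1", "TRDV2", "TRDV3")
  m[1:3, ] <- 0
  m["TRDV2", 1] <- 9                    # only TRDV2 -> Vd2pos
  m["TRDV1", 2] <- 8; m["TRDV2", 2] <- 3  # TRDV1 wins -> Vd2neg
  m["TRDV1", 3] <- 5; m["TRDV2", 3] <- 5  # tie -> unassigned
  # cell 4: all-zero Vdelta -> unassigned
  x <- assign_vd2_labels(gdx(m))
  expect_equal(x$cells$vd2_status, c("Vd2pos", "Vd2neg", NA, NA))
  expect_error(assign_vd2_labels(gdx(base_counts(5, 2))), "Vdelta genes")
})

test_that("expression-derived Vd2 labels agree with contig-derived labels", {
  sim <- simulate_repertoire(repertoire_sim_config(n_cells = 120, seed = 17))
  contig_lab <- sim$contigs %>%
    filter_productive() %>% reassign_hybrid_delta() %>%
    select_cell_chains() %>% pair_cells() %>% call_clonotypes()
  es <- simulate_expression(
    expression_sim_config(
      n_cells = 120, n_genes = 300, n_clusters = 2,
      vd_marker_genes = c(TRDV1 = 1L, TRDV2 = 2L), seed = 18
    ),
    cell_ids = sim$truth$barcode
  )
  # plant expression consistent with the contig truth: put each cell in the
  # cluster matching its delta V gene
  m <- as.matrix(es$counts)
  is_vd2 <- sim$truth$vd_gene == "TRDV2"
  m["TRDV2", ] <- ifelse(is_vd2, 20, 0)
  m["TRDV1", ] <- ifelse(is_vd2, 0, 20)
  x <- assign_vd2_labels(normalize_log(gdx(m)))
  joined <- dplyr::inner_join(
    contig_lab, tibble::tibble(barcode = x$cells$cell_id,
                               expr_status = x$cells$vd2_status),
    by = "barcode"
  )
  assigned <- !is.na(joined$expr_status)
  expect_gt(sum(assigned), 0)
  expect_equal(joined$vd2_status[assigned], joined$expr_status[assigned])
})

test_that("gene-set scores are zero on constant data and reproducible", {
  flat <- gdx(base_counts(60, 12, value = 3))
  sc <- gene_set_score(flat, c("G001", "G002"), n_bins = 5, ctrl_size = 5, seed = 1)
  expect_equal(as.numeric(sc), rep(0, 12))
  es <- simulate_expression(expression_sim_config(n_cells = 80, n_genes = 200, seed = 3))
  x <- normalize_log(qc_filter(gdx(es$counts), qc_thresholds(min_genes = 10)))
  s1 <- gene_set_score(x, paste0("SIG", 1:10), seed = 42)
  s2 <- gene_set_score(x, paste0("SIG", 1:10), seed = 42)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "n_overlap"), 10)
  expect_error(gene_set_score(x, c("NOT_A_GENE")), "overlap")
})

test_that("random gene sets score near zero on average", {
  es <- simulate_expression(expression_sim_config(
    n_cells = 150, n_genes = 300, n_clusters = 1, vd_marker_genes = c(),
    signature_effect = 0, seed = 23
  ))
  x <- normalize_log(qc_filter(gdx(es$counts), qc_thresholds(min_genes = 10)))
  set.seed(99)
  means <- replicate(100, {
    gs <- sample(rownames(x$counts), 15)
    mean(gene_set_score(x, gs, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("planted signature subpopulations score higher", {
  es <- simulate_expression(expression_sim_config(
    n_cells = 500, n_genes = 600, signature_effect = 1,
    vd_marker_genes = c(), seed = 31
  ))
  x <- normalize_log(qc_filter(gdx(es$counts, cell_meta = es$cell_meta)))
  sc <- gene_set_score(x, paste0("SIG", 1:25), seed = 7)
  bearing <- x$cells$signature_bearing
  p <- wilcox.test(sc[bearing], sc[!bearing])$p.value
  expect_lt(p, 0.01)
})

test_that("rank-sum DE matches the normal-approximation reference", {
  set.seed(8)
  m <- matrix(rpois(40 * 30, 5), 40, 30,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("C%02d", 1:30)))
  x <- normalize_log(gdx(m))
  tgt <- rep(c(TRUE, FALSE), each = 15)
  de <- wilcoxon_de(x, tgt, !tgt)
  for (g in c("G01", "G17", "G33")) {
    v <- as.numeric(x$logcounts[g, ])
    ref <- wilcox.test(v[tgt], v[!tgt], exact = FALSE, correct = FALSE)$p.value
    expect_equal(de$p_value[de$gene == g], ref, tolerance = 1e-10)
  }
  expect_true(all(de$p_adj >= de$p_value - 1e-12))
  # permutation invariance of the result set
  perm <- sample(ncol(m))
  de2 <- wilcoxon_de(normalize_log(gdx(m[, perm])), tgt[perm], !tgt[perm])
  expect_equal(dplyr::arrange(as.data.frame(de2), gene),
               dplyr::arrange(as.data.frame(de), gene))
})

test_that("DE on identical groups is null; planted genes lead the ranking", {
  m <- base_counts(20, 10, value = 4)
  m[] <- rep(seq_len(20), 10)  # every cell identical
  x <- normalize_log(gdx(m))
  de <- wilcoxon_de(x, rep(c(TRUE, FALSE), 5), rep(c(FALSE, TRUE), 5))
  expect_true(all(de$p_value > 0.99))
  expect_true(all(abs(de$logfc) < 1e-9))

  es <- simulate_expression(expression_sim_config(
    n_cells = 300, n_genes = 200, planted_signature_genes = "SIG1",
    signature_effect = 2.5, vd_marker_genes = c(), seed = 6
  ))
  x2 <- normalize_log(qc_filter(gdx(es$counts, cell_meta = es$cell_meta),
                                qc_thresholds(min_genes = 10)))
  de2 <- wilcoxon_de(x2, x2$cells$true_cluster == 1, x2$cells$true_cluster == 2)
  expect_equal(de2$gene[which.min(de2$p_adj)], "SIG1")
  expect_error(wilcoxon_de(x2, rep(FALSE, ncol(x2$counts)),
                           x2$cells$true_cluster == 2), "non-empty")
})

test_that("signature derivation takes top-k upregulated with stable ties", {
  de <- tibble::tibble(
    gene = c("up1", "up2", "up3", "down1"),
    statistic = 1, z = c(3, 2, 2, -3),
    p_value = c(0.001, 0.01, 0.01, 0.001),
    p_adj = p.adjust(c(0.001, 0.01, 0.01, 0.001), "BH"),
    logfc = c(1, 0.5, 0.9, -1),
    logfc_display = c(1, 0.5, 0.9, -1),
    direction = c("up", "up", "up", "down")
  )
  class(de) <- c("gdtcr_de", class(de))
  sig <- derive_signature(de, k = 2)
  expect_equal(sig$gene, c("up1", "up3"))  # tie broken by larger logfc
  expect_warning(all_up <- derive_signature(de, k = 10), "returning all")
  expect_equal(nrow(all_up), 3)
  # input permutation changes nothing
  sig2 <- derive_signature(de[sample(4), ], k = 2)
  expect_equal(sig2$gene, sig$gene)
})

test_that("signatures round-trip through JSON", {
  de <- tibble::tibble(
    gene = paste0("G", 1:5), statistic = 1:5, z = 5:1,
    p_value = (1:5) / 100, p_adj = (1:5) / 50,
    logfc = rep(1, 5), logfc_display = rep(1, 5), direction = "up"
  )
  class(de) <- c("gdtcr_de", class(de))
  sig <- derive_signature(de, k = 3, contrast = "demo")
  f <- tempfile(fileext = ".json")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$gene, sig$gene)
  expect_equal(attr(back, "contrast"), "demo")
})
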