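.contig_cols <- c(
  "sample_id", "barcode", "contig_id", "chain", "v_gene", "d_gene", "j_gene",
  "c_gene", "full_length", "productive", "cdr3_aa", "cdr3_nt", "sequence_nt",
  "umis", "reads"
)

.parse_flag <- function(x) {
  x <- trimws(as.character(x))
  up <- toupper(x)
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "YES", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "NO", "0")] <- FALSE
  out
}

.blank_if_na <- function(x) {
  x <- as.character(x)
  x[is.na(x) | toupper(x) %in% c("NA", "NONE", "NULL")] <- ""
  x
}

#' Read a contig annotation table
#'
#' Reads 10x-style `all_contig_annotations.csv` (`dialect = "tenx_csv"`) or an
#' AIRR rearrangement TSV (`dialect = "airr_tsv"`) into the package's
#' normalized contig schema. Dialect truth strings (`"True"`, `"T"`, ...) are
#' mapped to logical; `"None"`-like productive calls become `NA` (unknown),
#' and the record is retained for rule-based re-evaluation. Missing gene calls
#' become empty strings.
#'
#' @param path Path to the file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @param sample_id Sample label to attach when the file carries none.
#' @return A contig tibble with columns `sample_id`, `barcode`, `contig_id`,
#'   `chain`, `v_gene`, `d_gene`, `j_gene`, `c_gene`, `full_length`,
#'   `productive`, `cdr3_aa`, `cdr3_nt`, `sequence_nt`, `umis`, `reads`.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv"),
                         sample_id = "sample1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- if (dialect == "tenx_csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  if (nrow(raw) == 0) {
    warn("contig file is empty; returning an empty table.")
    return(tibble::as_tibble(setNames(
      rep(list(character(0)), length(.contig_cols)), .contig_cols
    )))
  }
  need <- if (dialect == "tenx_csv") {
    c("barcode", "contig_id", "chain", "v_gene", "j_gene", "productive",
      "full_length", "cdr3", "cdr3_nt", "umis")
  } else {
    c("cell_id", "sequence_id", "locus", "v_call", "j_call", "productive",
      "junction", "junction_aa")
  }
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("contig file is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  get0c <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep("", nrow(raw))
  out <- if (dialect == "tenx_csv") {
    tibble(
      sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else sample_id,
      barcode = raw$barcode,
      contig_id = raw$contig_id,
      chain = toupper(.blank_if_na(raw$chain)),
      v_gene = .blank_if_na(raw$v_gene),
      d_gene = .blank_if_na(get0c("d_gene")),
      j_gene = .blank_if_na(raw$j_gene),
      c_gene = .blank_if_na(get0c("c_gene")),
      full_length = .parse_flag(raw$full_length),
      productive = .parse_flag(raw$productive),
      cdr3_aa = .blank_if_na(raw$cdr3),
      cdr3_nt = .blank_if_na(raw$cdr3_nt),
      sequence_nt = .blank_if_na(get0c("sequence")),
      umis = as.integer(raw$umis),
      reads = suppressWarnings(as.integer(get0c("reads")))
    )
  } else {
    tibble(
      sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else sample_id,
      barcode = raw$cell_id,
      contig_id = raw$sequence_id,
      chain = toupper(.blank_if_na(raw$locus)),
      v_gene = .blank_if_na(raw$v_call),
      d_gene = .blank_if_na(get0c("d_call")),
      j_gene = .blank_if_na(raw$j_call),
      c_gene = .blank_if_na(get0c("c_call")),
      full_length = .parse_flag(get0c("complete_vdj")),
      productive = .parse_flag(raw$productive),
      cdr3_aa = .blank_if_na(raw$junction_aa),
      cdr3_nt = .blank_if_na(raw$junction),
      sequence_nt = .blank_if_na(get0c("sequence")),
      umis = suppressWarnings(as.integer(get0c("duplicate_count"))),
      reads = suppressWarnings(as.integer(get0c("consensus_count")))
    )
  }
  out$reads[is.na(out$reads)] <- 0L
  out$umis[is.na(out$umis)] <- 0L
  chains <- c("TRG", "TRD", "TRA", "TRB")
  out$chain[!out$chain %in% chains] <- ifelse(
    nzchar(out$chain[!out$chain %in% chains]), "other", "other"
  )
  out
}

#' Write a contig table in the 10x annotation CSV dialect
#'
#' Inverse of [read_contigs()] with `dialect = "tenx_csv"`; a written file
#' read back and re-written is byte-identical.
#'
#' @param contigs Normalized contig tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_tenx <- function(contigs, path) {
  out <- tibble(
    sample_id = contigs$sample_id,
    barcode = contigs$barcode,
    contig_id = contigs$contig_id,
    chain = ifelse(contigs$chain == "other", "Multi", contigs$chain),
    v_gene = contigs$v_gene, d_gene = contigs$d_gene,
    j_gene = contigs$j_gene, c_gene = contigs$c_gene,
    full_length = ifelse(is.na(contigs$full_length), "None",
                         ifelse(contigs$full_length, "True", "False")),
    productive = ifelse(is.na(contigs$productive), "None",
                        ifelse(contigs$productive, "True", "False")),
    cdr3 = contigs$cdr3_aa, cdr3_nt = contigs$cdr3_nt,
    sequence = contigs$sequence_nt,
    umis = contigs$umis, reads = contigs$reads
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a contig table as an AIRR rearrangement TSV
#'
#' @param contigs Normalized contig tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_airr <- function(contigs, path) {
  out <- tibble(
    sample_id = contigs$sample_id,
    cell_id = contigs$barcode,
    sequence_id = contigs$contig_id,
    locus = ifelse(contigs$chain == "other", "", contigs$chain),
    v_call = contigs$v_gene, d_call = contigs$d_gene,
    j_call = contigs$j_gene, c_call = contigs$c_gene,
    complete_vdj = ifelse(is.na(contigs$full_length), "",
                          ifelse(contigs$full_length, "T", "F")),
    productive = ifelse(is.na(contigs$productive), "",
                        ifelse(contigs$productive, "T", "F")),
    junction = contigs$cdr3_nt, junction_aa = contigs$cdr3_aa,
    sequence = contigs$sequence_nt,
    duplicate_count = contigs$umis, consensus_count = contigs$reads
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a sparse count matrix as MTX plus barcode and feature TSVs
#'
#' Standard 10x-style trio: `matrix.mtx`, `barcodes.tsv`, `features.tsv`
#' inside `dir`.
#'
#' @param counts Genes x cells sparse matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir` (writer) or the counts matrix (reader), invisibly for the
#'   writer.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(barcode = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble(gene = rownames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE, progress = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  bc <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                        col_types = "c", progress = FALSE)
  ft <- readr::read_tsv(file.path(dir, "features.tsv"), col_names = "gene",
                        col_types = "c", progress = FALSE)
  dimnames(m) <- list(ft$gene, bc$barcode)
  m
}
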