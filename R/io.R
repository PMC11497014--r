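# readers/writers for the pipeline's on-disk formats: 10x-style contig CSV,
# MatrixMarket counts with features/barcodes sidecars, metadata and bulk TSVs,
# and the simulation truth JSON

#' Write simulated cells as a 10x-style filtered contig CSV
#'
#' Emits two productive contig rows (TRA and TRB) per cell so that the file
#' round-trips through [read_contigs()] + [collapse_to_clonotypes()] to the
#' cells' original paired clonotype keys.
#'
#' @param cells Cell table from [simulate_pair()] (needs barcode, subject_id,
#'   cdr3_tra, cdr3_trb).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_10x <- function(cells, path) {
  stopifnot(all(c("barcode", "subject_id", "cdr3_tra", "cdr3_trb") %in%
                  names(cells)))
  rows <- data.frame(
    barcode = rep(cells$barcode, 2L),
    sample = rep(cells$subject_id, 2L),
    is_cell = "true",
    high_confidence = "true",
    chain = rep(c("TRA", "TRB"), each = nrow(cells)),
    cdr3 = c(cells$cdr3_tra, cells$cdr3_trb),
    productive = "true",
    umis = 2L,
    reads = 10L,
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$barcode, rows$chain), , drop = FALSE]
  data.table::fwrite(rows, path, sep = ",")
  invisible(path)
}

#' Write and read the canonical cell metadata TSV
#'
#' Columns: barcode, sample_id, subject_id, pair_id, role, group, subset.
#' @param cells Cell table (e.g. from [simulate_pair()]).
#' @param path TSV path.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_cell_metadata <- function(cells, path) {
  cols <- intersect(c("barcode", "sample_id", "subject_id", "pair_id",
                      "role", "group", "subset"), names(cells))
  md <- cells[, cols, drop = FALSE]
  if (!"sample_id" %in% names(md)) md$sample_id <- md$subject_id
  data.table::fwrite(md, path, sep = "\t")
  invisible(path)
}

#' @rdname write_cell_metadata
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' Write and read gene x cell counts as MatrixMarket + sidecar TSVs
#'
#' Writes `<prefix>.mtx`, `<prefix>.features.tsv` and `<prefix>.barcodes.tsv`.
#' @param counts genes x cells matrix with dimnames.
#' @param prefix Path prefix for the three files.
#' @return The prefix (writer) or a dense genes x cells matrix (reader).
#' @export
write_counts_mtx <- function(counts, prefix) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  data.table::fwrite(data.frame(gene = rownames(counts)),
                     paste0(prefix, ".features.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(barcode = colnames(counts)),
                     paste0(prefix, ".barcodes.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  mtx <- paste0(prefix, ".mtx")
  if (!file.exists(mtx)) stopf("counts matrix not found: %s", mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- data.table::fread(paste0(prefix, ".features.tsv"),
                                   header = FALSE, data.table = FALSE)[[1L]]
  colnames(m) <- data.table::fread(paste0(prefix, ".barcodes.tsv"),
                                   header = FALSE, data.table = FALSE)[[1L]]
  m
}

#' Write and read a genes x samples bulk expression TSV
#' @param bulk genes x samples matrix with dimnames.
#' @param path TSV path (first column `gene`).
#' @return `path` (writer) or a matrix (reader).
#' @export
write_bulk_tsv <- function(bulk, path) {
  df <- data.frame(gene = rownames(bulk), as.data.frame(bulk),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_bulk_tsv
#' @export
read_bulk_tsv <- function(path) {
  if (!file.exists(path)) stopf("bulk expression file not found: %s", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", data.table = FALSE))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write the hidden simulation labels as a JSON sidecar
#' @param truth Truth list (per-cell origins, mixture weights, ...).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  keep <- truth[setdiff(names(truth), "donor_pool")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
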