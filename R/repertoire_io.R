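#' Read TCR contig annotations from 10x or AIRR files
#'
#' Parses either a 10x Genomics `filtered_contig_annotations.csv` or an AIRR
#' Rearrangement TSV into a canonical contig table. Productivity strings are
#' parsed case-insensitively (`"true"`/`"T"` and variants); loci other than
#' TRA/TRB are mapped to chain `"other"`.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx_csv"` (mandatory columns: barcode, chain, cdr3,
#'   productive, umis, reads) or `"airr_tsv"` (cell_id, locus, junction_aa,
#'   productive, duplicate_count).
#' @return A data.frame with columns `barcode`, `sample_id`, `chain`
#'   (`TRA`/`TRB`/`other`), `cdr3_aa`, `productive` (logical), `umis`, `reads`.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("contig file not found: %s", path)
  sep <- if (dialect == "tenx_csv") "," else "\t"
  df <- as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                        colClasses = NULL, data.table = FALSE,
                                        na.strings = c("NA", "None")))
  if (!nrow(df)) {
    if (!ncol(df)) stopf("contig file has no header: %s", path)
    warnf("contig file is empty: %s", path)
  }
  if (dialect == "tenx_csv") {
    assert_columns(df, c("barcode", "chain", "cdr3", "productive",
                         "umis", "reads"), "tenx_csv contig file")
    out <- data.frame(
      barcode = as.character(df$barcode),
      sample_id = if ("sample" %in% names(df)) as.character(df$sample)
                  else rep(NA_character_, nrow(df)),
      chain = as.character(df$chain),
      cdr3_aa = as.character(df$cdr3),
      productive = parse_productive(df$productive),
      umis = as.integer(df$umis),
      reads = as.integer(df$reads),
      stringsAsFactors = FALSE)
  } else {
    assert_columns(df, c("cell_id", "locus", "junction_aa", "productive",
                         "duplicate_count"), "airr_tsv rearrangement file")
    out <- data.frame(
      barcode = as.character(df$cell_id),
      sample_id = if ("sample_id" %in% names(df)) as.character(df$sample_id)
                  else rep(NA_character_, nrow(df)),
      chain = as.character(df$locus),
      cdr3_aa = as.character(df$junction_aa),
      productive = parse_productive(df$productive),
      umis = as.integer(df$duplicate_count),
      reads = if ("consensus_count" %in% names(df))
        as.integer(df$consensus_count) else rep(0L, nrow(df)),
      stringsAsFactors = FALSE)
  }
  out$chain[!out$chain %in% c("TRA", "TRB")] <- "other"
  out$cdr3_aa[is.na(out$cdr3_aa)] <- ""
  out$umis[is.na(out$umis)] <- 0L
  out$reads[is.na(out$reads)] <- 0L
  out
}

parse_productive <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Keep cells with at least one productive TRA or TRB contig
#'
#' A barcode is kept iff it has at least one productive TRA or TRB contig with
#' a non-empty CDR3 amino-acid sequence; all contigs of dropped barcodes are
#' removed, and non-productive (or CDR3-less) contigs of kept barcodes are
#' removed too. Idempotent and never increases the barcode count.
#'
#' @param contigs Contig table from [read_contigs()].
#' @return A list with `contigs` (the filtered table) and `keep` (named
#'   logical vector over the input barcodes).
#' @export
filter_productive <- function(contigs) {
  if (!nrow(contigs)) {
    return(list(contigs = contigs, keep = stats::setNames(logical(0), character(0))))
  }
  informative <- contigs$productive & contigs$chain %in% c("TRA", "TRB") &
    nzchar(contigs$cdr3_aa)
  kept_barcodes <- unique(contigs$barcode[informative])
  keep <- stats::setNames(unique(contigs$barcode) %in% kept_barcodes,
                          unique(contigs$barcode))
  sel <- contigs$barcode %in% kept_barcodes & contigs$productive &
    nzchar(contigs$cdr3_aa)
  list(contigs = contigs[sel, , drop = FALSE], keep = keep)
}

#' Collapse productive contigs to one clonotype key per cell
#'
#' Per barcode and locus, when several productive contigs exist the one with
#' the highest UMI count is kept (ties broken by read count, then by the
#' lexicographically smallest CDR3). The clonotype key is the kept TRA and TRB
#' CDR3s joined as `"TRA:<aa>|TRB:<aa>"`, with a missing locus rendered as
#' `"TRA:-"` / `"TRB:-"`; `chain_mode` restricts which loci enter the key.
#' Matching downstream is exact, case-sensitive string equality.
#'
#' @param contigs Productivity-filtered contig table ([filter_productive()]).
#' @param chain_mode `"both"` (paired key, the default), `"trb_only"` or
#'   `"tra_only"`; in single-chain modes cells lacking that chain are dropped
#'   with a warning.
#' @param metadata Cell metadata data.frame with columns `barcode`,
#'   `subject_id`, `pair_id`, `role`, `group` and optionally `subset`;
#'   barcodes absent from the metadata are dropped with a warning.
#' @return A data.frame of cell clonotypes: barcode, subject_id, pair_id,
#'   role, group, subset, clonotype_key.
#' @export
collapse_to_clonotypes <- function(contigs,
                                   chain_mode = c("both", "trb_only", "tra_only"),
                                   metadata) {
  chain_mode <- match.arg(chain_mode)
  assert_columns(metadata, c("barcode", "subject_id", "pair_id", "role",
                             "group"), "cell metadata")
  contigs <- contigs[contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  if (!nrow(contigs))
    return(empty_clonotype_table())

  # deterministic best-contig-per-(barcode, locus): highest umis, then reads,
  # then lexicographically smallest cdr3
  ord <- order(contigs$barcode, contigs$chain, -contigs$umis, -contigs$reads,
               contigs$cdr3_aa)
  contigs <- contigs[ord, , drop = FALSE]
  first <- !duplicated(contigs[, c("barcode", "chain")])
  best <- contigs[first, , drop = FALSE]

  barcodes <- unique(best$barcode)
  tra <- stats::setNames(rep(NA_character_, length(barcodes)), barcodes)
  trb <- tra
  a <- best[best$chain == "TRA", ]
  b <- best[best$chain == "TRB", ]
  tra[a$barcode] <- a$cdr3_aa
  trb[b$barcode] <- b$cdr3_aa

  key <- switch(chain_mode,
    both = paste0("TRA:", ifelse(is.na(tra), "-", tra),
                  "|TRB:", ifelse(is.na(trb), "-", trb)),
    trb_only = ifelse(is.na(trb), NA_character_, paste0("TRB:", trb)),
    tra_only = ifelse(is.na(tra), NA_character_, paste0("TRA:", tra)))
  keep <- !is.na(key)
  if (any(!keep))
    warnf("%d cell(s) lack the %s chain and were dropped", sum(!keep),
          if (chain_mode == "trb_only") "TRB" else "TRA")
  cells <- data.frame(barcode = barcodes[keep], clonotype_key = key[keep],
                      stringsAsFactors = FALSE)

  unmatched <- !cells$barcode %in% metadata$barcode
  if (any(unmatched))
    warnf("%d cell(s) missing from the metadata were dropped", sum(unmatched))
  cells <- cells[!unmatched, , drop = FALSE]
  md <- metadata[match(cells$barcode, metadata$barcode), , drop = FALSE]
  data.frame(barcode = cells$barcode,
             subject_id = md$subject_id,
             pair_id = md$pair_id,
             role = md$role,
             group = md$group,
             subset = if ("subset" %in% names(md)) md$subset else NA_character_,
             clonotype_key = cells$clonotype_key,
             stringsAsFactors = FALSE)
}

empty_clonotype_table <- function() {
  data.frame(barcode = character(0), subject_id = character(0),
             pair_id = character(0), role = character(0),
             group = character(0), subset = character(0),
             clonotype_key = character(0), stringsAsFactors = FALSE)
}
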