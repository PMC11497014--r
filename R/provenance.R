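#' Classify paired donor-recipient clonotypes as consistent or unique
#'
#' A clonotype is *consistent* iff its key occurs in both the donor's and the
#' recipient's clonotype sets, and *unique* otherwise; every cell inherits its
#' clonotype's label. Consistent clonotypes proxy peripheral-pathway
#' reconstitution (expansion of transferred mature donor T cells),
#' recipient-unique clonotypes proxy central-pathway (de novo thymic) output.
#'
#' @param donor_cells,recipient_cells Cell clonotype tables (as produced by
#'   [collapse_to_clonotypes()] or [simulate_pair()]); both non-empty, same
#'   `pair_id`.
#' @return An object of class `provenance_pair`: list with `pair_id`, `group`,
#'   `consistent_keys`, `cells` (both roles row-bound with a `label` column),
#'   and `counts` (per role: cells/clonotypes by label).
#' @examples
#' d <- data.frame(barcode = c("d1", "d2"), pair_id = "P", role = "donor",
#'                 group = "MSDT", subset = "Teff", clonotype_key = c("X", "Y"))
#' r <- data.frame(barcode = c("r1", "r2", "r3"), pair_id = "P",
#'                 role = "recipient", group = "MSDT", subset = "Teff",
#'                 clonotype_key = c("X", "X", "Z"))
#' p <- classify_clonotypes(d, r)
#' subset(p$cells, role == "recipient")$label  # consistent, consistent, unique
#' @export
classify_clonotypes <- function(donor_cells, recipient_cells) {
  if (is.null(donor_cells) || !nrow(donor_cells))
    stopf("donor cell table is empty")
  if (is.null(recipient_cells) || !nrow(recipient_cells))
    stopf("recipient cell table is empty")
  for (df in list(donor_cells, recipient_cells))
    assert_columns(df, c("barcode", "pair_id", "role", "clonotype_key"),
                   "cell clonotype table")
  pid_d <- unique(donor_cells$pair_id)
  pid_r <- unique(recipient_cells$pair_id)
  if (length(pid_d) != 1L || length(pid_r) != 1L || pid_d != pid_r)
    stopf("donor and recipient tables must share a single pair_id (got '%s' vs '%s')",
          paste(pid_d, collapse = ","), paste(pid_r, collapse = ","))

  donor_keys <- unique(donor_cells$clonotype_key)
  recip_keys <- unique(recipient_cells$clonotype_key)
  consistent <- intersect(donor_keys, recip_keys)

  cells <- rbind(
    donor_cells[, intersect(names(donor_cells),
                            c("barcode", "subject_id", "pair_id", "role",
                              "group", "subset", "clonotype_key"))],
    recipient_cells[, intersect(names(recipient_cells),
                                c("barcode", "subject_id", "pair_id", "role",
                                  "group", "subset", "clonotype_key"))])
  cells$label <- ifelse(cells$clonotype_key %in% consistent,
                        "consistent", "unique")

  counts <- do.call(rbind, lapply(c("donor", "recipient"), function(rl) {
    cc <- cells[cells$role == rl, ]
    keys <- unique(cc$clonotype_key)
    data.frame(role = rl,
               n_cells = nrow(cc),
               n_clonotypes = length(keys),
               n_cells_consistent = sum(cc$label == "consistent"),
               n_cells_unique = sum(cc$label == "unique"),
               n_clonotypes_consistent = sum(keys %in% consistent),
               n_clonotypes_unique = sum(!keys %in% consistent),
               stringsAsFactors = FALSE)
  }))

  structure(list(pair_id = pid_d,
                 group = unique(c(donor_cells$group, recipient_cells$group))[1L],
                 consistent_keys = consistent,
                 cells = cells,
                 counts = counts),
            class = "provenance_pair")
}

#' @export
print.provenance_pair <- function(x, ...) {
  cat(sprintf("provenance_pair '%s' (%s): %d consistent clonotype(s)\n",
              x$pair_id, x$group %||% "?", length(x$consistent_keys)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Tabulate provenance fractions per role and T-cell subset
#'
#' Computes, within each (role, subset) stratum of a classified pair, the
#' fractions of cells and of distinct clonotypes that are consistent vs
#' unique. A pooled `"all"` stratum is always included; strata with fewer
#' than `min_cells` cells are still reported but flagged `low_confidence`.
#'
#' @param pair A `provenance_pair` from [classify_clonotypes()].
#' @param min_cells Minimum stratum size for a confident estimate.
#' @param merge_map Optional named character vector renaming subsets before
#'   tabulation (e.g. merging ZNF683-high and -low effector clusters:
#'   `c("CD8 Teff:ZNF683hi" = "CD8 Teff", "CD8 Teff:ZNF683lo" = "CD8 Teff")`).
#' @return A data.frame with one row per (pair_id, role, subset): n_cells,
#'   n_clonotypes, consistent/unique cell and clonotype fractions, and a
#'   `low_confidence` flag.
#' @export
provenance_by_subset <- function(pair, min_cells = 10L, merge_map = NULL) {
  stopifnot(inherits(pair, "provenance_pair"))
  cells <- pair$cells
  if (all(is.na(cells$subset)))
    stopf("no subset labels present; join cell-type annotations first")
  if (!is.null(merge_map)) {
    hit <- cells$subset %in% names(merge_map)
    cells$subset[hit] <- merge_map[cells$subset[hit]]
  }
  cells <- cells[!is.na(cells$subset), , drop = FALSE]

  strata <- rbind(
    unique(cells[, c("role", "subset")]),
    data.frame(role = c("donor", "recipient"), subset = "all"))
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    rl <- strata$role[i]; ss <- strata$subset[i]
    cc <- cells[cells$role == rl & (ss == "all" | cells$subset == ss), ]
    if (!nrow(cc)) return(NULL)
    keys <- unique(cc$clonotype_key)
    kc <- keys %in% pair$consistent_keys
    data.frame(pair_id = pair$pair_id, group = pair$group,
               role = rl, subset = ss,
               n_cells = nrow(cc), n_clonotypes = length(keys),
               consistent_cell_fraction = mean(cc$label == "consistent"),
               unique_cell_fraction = mean(cc$label == "unique"),
               consistent_clonotype_fraction = mean(kc),
               unique_clonotype_fraction = mean(!kc),
               low_confidence = nrow(cc) < min_cells,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$role, out$subset), , drop = FALSE]
}

#' Contrast provenance fractions between transplant groups
#'
#' For each subset, compares the per-pair fractions (default: the recipient
#' unique-cell fraction) between the two transplant groups with a two-sided
#' exact rank-sum test ([rank_sum_test()]) and adjusts across subsets with
#' Benjamini-Hochberg ([bh_adjust()]). With a single pair in a group the
#' contrast is reported descriptively (p not computable).
#'
#' @param summaries Row-bound [provenance_by_subset()] tables across pairs.
#' @param metric Column to contrast (default `"unique_cell_fraction"`).
#' @param role Role whose fractions are contrasted (default `"recipient"`).
#' @param groups The two group labels (default `c("haplo", "MSDT")`).
#' @return A data.frame per subset: per-group means and n, difference
#'   (first group minus second), rank-sum p, BH-adjusted p.
#' @export
group_provenance_contrast <- function(summaries,
                                      metric = "unique_cell_fraction",
                                      role = "recipient",
                                      groups = c("haplo", "MSDT")) {
  assert_columns(summaries, c("pair_id", "group", "role", "subset", metric),
                 "provenance summaries")
  s <- summaries[summaries$role == role, , drop = FALSE]
  for (g in groups)
    if (!any(s$group == g)) stopf("group '%s' has zero pairs", g)

  out <- do.call(rbind, lapply(unique(s$subset), function(ss) {
    x <- s[s$subset == ss & s$group == groups[1L], metric]
    y <- s[s$subset == ss & s$group == groups[2L], metric]
    p <- if (length(x) >= 2L && length(y) >= 2L)
      rank_sum_test(x, y)$p_value else NA_real_
    data.frame(subset = ss,
               mean_group1 = mean(x), n_group1 = length(x),
               mean_group2 = mean(y), n_group2 = length(y),
               difference = mean(x) - mean(y),
               p_value = p, stringsAsFactors = FALSE)
  }))
  names(out)[names(out) == "mean_group1"] <- paste0("mean_", groups[1L])
  names(out)[names(out) == "mean_group2"] <- paste0("mean_", groups[2L])
  names(out)[names(out) == "n_group1"] <- paste0("n_", groups[1L])
  names(out)[names(out) == "n_group2"] <- paste0("n_", groups[2L])
  computable <- !is.na(out$p_value)
  out$adjusted_p <- NA_real_
  if (any(computable))
    out$adjusted_p[computable] <- bh_adjust(out$p_value[computable])
  rownames(out) <- NULL
  out
}
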