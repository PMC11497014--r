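#' Shannon diversity index of a clone-size distribution
#'
#' `H = -sum(p_i * log(p_i))` with `p_i = count_i / sum(counts)`, in natural-log
#' units by default. `H` is 0 for a single clone and attains its maximum
#' `log(K)` when all `K` clones are equally abundant.
#'
#' @param counts Non-empty vector of positive clone sizes.
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative scalar diversity.
#' @examples
#' shannon_index(c(10, 10, 10, 10))  # log(4)
#' shannon_index(c(3, 1))            # 0.5623351...
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (!length(counts)) stopf("'counts' must be non-empty")
  if (any(is.na(counts)) || any(counts <= 0))
    stopf("'counts' must be positive")
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Pielou evenness of a clone-size distribution
#'
#' `J = H / log(K)`; `NA` when only one clonotype is present.
#' @inheritParams shannon_index
#' @return Evenness in `[0, 1]`, or `NA` for a single clone.
#' @export
pielou_evenness <- function(counts, base = exp(1)) {
  k <- length(counts)
  if (k < 2L) return(NA_real_)
  shannon_index(counts, base) / (log(k) / log(base))
}

#' Per-stratum TCR repertoire diversity
#'
#' Tabulates clone sizes per stratum (per subject, or per subject x subset)
#' and computes the Shannon index and Pielou evenness. Strata smaller than
#' `min_cells` are flagged `low_confidence`; when every stratum is below the
#' threshold an empty table is returned with a warning. An optional rarefied
#' Shannon (mean over seeded random subsamples of a fixed size) is available
#' because strata differ in size.
#'
#' @param cells Cell clonotype table (needs `subject_id`, `clonotype_key`, and
#'   `subset` for per-subset strata; `pair_id`, `role`, `group` are carried
#'   through when present).
#' @param strata `"per_sample"` or `"per_sample_subset"`.
#' @param min_cells Minimum confident stratum size.
#' @param subsample_to Optional rarefaction depth (cells); strata smaller than
#'   this get `NA` rarefied values.
#' @param n_subsamples Number of random subsamples for rarefaction.
#' @param seed Seed for the rarefaction subsampling.
#' @return A data.frame per stratum: identifiers, n_cells, n_clonotypes,
#'   shannon, pielou, low_confidence (and shannon_rarefied when requested).
#' @export
diversity_by_group <- function(cells,
                               strata = c("per_sample", "per_sample_subset"),
                               min_cells = 10L, subsample_to = NULL,
                               n_subsamples = 50L, seed = 1L) {
  strata <- match.arg(strata)
  assert_columns(cells, c("subject_id", "clonotype_key"), "cell table")
  if (strata == "per_sample_subset")
    assert_columns(cells, "subset", "cell table (per-subset strata)")

  key_cols <- if (strata == "per_sample") "subject_id"
              else c("subject_id", "subset")
  cells$.stratum <- do.call(paste, c(cells[key_cols], sep = "|"))
  carried <- intersect(c("pair_id", "role", "group"), names(cells))

  if (!is.null(subsample_to)) set.seed(seed)
  rows <- lapply(split(cells, cells$.stratum), function(cc) {
    counts <- as.integer(table(cc$clonotype_key))
    row <- data.frame(stratum = cc$.stratum[1L],
                      subject_id = cc$subject_id[1L],
                      subset = if (strata == "per_sample_subset")
                        cc$subset[1L] else NA_character_,
                      n_cells = nrow(cc),
                      n_clonotypes = length(counts),
                      shannon = shannon_index(counts),
                      pielou = pielou_evenness(counts),
                      low_confidence = nrow(cc) < min_cells,
                      stringsAsFactors = FALSE)
    for (col in carried) row[[col]] <- cc[[col]][1L]
    if (!is.null(subsample_to)) {
      row$shannon_rarefied <- if (nrow(cc) < subsample_to) NA_real_ else
        mean(vapply(seq_len(n_subsamples), function(i) {
          sub <- sample(cc$clonotype_key, subsample_to)
          shannon_index(as.integer(table(sub)))
        }, numeric(1)))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out) && all(out$low_confidence)) {
    warnf("all strata have fewer than %d cells", min_cells)
    return(out[0L, , drop = FALSE])
  }
  out
}
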