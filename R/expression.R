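#' Library-size normalize counts to a fixed total and log1p-transform
#'
#' Each cell's counts are scaled so its total equals `target` (10^4 by
#' default) and the normalized values are transformed as `log(1 + x)`.
#' All-zero cells are dropped with a warning.
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param target Per-cell total after normalization (default `1e4`).
#' @return genes x cells matrix of log1p-normalized expression, with attribute
#'   `normalization_target`.
#' @examples
#' m <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(paste0("g", 1:3), "c1"))
#' expm1(normalize_counts(m))  # 2500, 2500, 5000
#' @export
normalize_counts <- function(counts, target = 1e4) {
  assert_scalar_number(target, "target", lower = 0, strict_lower = TRUE)
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stopf("counts must be integers")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    warnf("dropping %d all-zero cell(s)", sum(cs == 0))
    counts <- counts[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  logmat <- log1p(sweep(counts, 2L, target / cs, `*`))
  attr(logmat, "normalization_target") <- target
  logmat
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Genes are ranked by the dispersion (variance / mean) of their normalized
#' expression (recovered from the log layer as `expm1`), z-scored within 20
#' equal-frequency bins of mean expression so that highly expressed genes do
#' not dominate. The top `n` expressed genes are returned; if fewer genes are
#' expressed, all are returned with a warning.
#'
#' @param logmat log1p-normalized genes x cells matrix ([normalize_counts()]).
#' @param n Number of genes to select (default 2000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of selected gene ids, most variable first.
#' @export
select_hvg <- function(logmat, n = 2000L, n_bins = 20L) {
  assert_scalar_number(n, "n", lower = 1)
  norm <- expm1(logmat)
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  expressed <- mu > 0
  if (sum(expressed) < n) {
    warnf("only %d expressed gene(s) available (requested %d)",
          sum(expressed), n)
    n <- sum(expressed)
  }
  disp <- v[expressed] / mu[expressed]
  m <- mu[expressed]
  bins <- cut(rank(m, ties.method = "first"),
              breaks = min(n_bins, length(m)), labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  names(sort(z, decreasing = TRUE))[seq_len(n)]
}

#' One-vs-rest Wilcoxon marker ranking with log2 fold-change thresholding
#'
#' For each cluster, every gene is tested cluster-vs-rest with a two-sided
#' rank-sum test (normal approximation with tie correction; exhaustive exact
#' enumeration when both groups are small, see [rank_sum_test()]). The log2
#' fold change is the difference of mean log1p-normalized expression divided
#' by `ln 2`. P-values are Benjamini-Hochberg adjusted per cluster across
#' genes, and a gene is flagged significant when `log2_fold_change > lfc_min`
#' and `adjusted_p < padj_max` (defaults 0.1 and 0.05). Genes are ranked
#' within cluster by p-value, ties broken by |log2FC|.
#'
#' @param logmat log1p-normalized genes x cells matrix.
#' @param labels Cluster label per cell (length `ncol(logmat)`).
#' @param lfc_min Log2 fold-change threshold (exclusive).
#' @param padj_max Adjusted-p threshold (exclusive).
#' @return A data.frame: cluster, gene, log2_fold_change, p_value, adjusted_p,
#'   rank_within_cluster, significant.
#' @export
rank_markers_wilcoxon <- function(logmat, labels, lfc_min = 0.1,
                                  padj_max = 0.05) {
  labels <- as.character(labels)
  if (length(labels) != ncol(logmat))
    stopf("'labels' must have one entry per cell")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warnf("excluding cluster(s) with < 2 cells: %s",
          paste(small, collapse = ", "))
    keep <- !labels %in% small
    logmat <- logmat[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stopf("need at least 2 clusters with >= 2 cells")

  # per-gene ranks and tie sums are cluster-independent: compute once
  ranks <- t(apply(logmat, 1L, rank))
  tie_sum <- apply(ranks, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  n_total <- ncol(logmat)

  out <- do.call(rbind, lapply(clusters, function(cl) {
    in_cl <- labels == cl
    m <- sum(in_cl)
    n <- n_total - m
    w <- rowSums(ranks[, in_cl, drop = FALSE])
    if (choose(n_total, m) <= choose(16, 8)) {
      p <- vapply(seq_len(nrow(logmat)), function(g)
        rank_sum_test(logmat[g, in_cl], logmat[g, !in_cl])$p_value, numeric(1))
    } else {
      p <- ranksum_normal_p(w, m, n, tie_sum)
    }
    lfc <- (rowMeans(logmat[, in_cl, drop = FALSE]) -
              rowMeans(logmat[, !in_cl, drop = FALSE])) / log(2)
    padj <- bh_adjust(p)
    df <- data.frame(cluster = cl, gene = rownames(logmat),
                     log2_fold_change = lfc, p_value = p, adjusted_p = padj,
                     significant = lfc > lfc_min & padj < padj_max,
                     stringsAsFactors = FALSE)
    df$rank_within_cluster <- order(order(df$p_value, -abs(df$log2_fold_change)))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Build top-k signature programs from a marker table
#'
#' Per cluster, takes the `k` best significant markers (by
#' `rank_within_cluster`) after removing T-cell receptor locus genes
#' (identifiers matching `^TR[ABGD][VDJC]`), which would otherwise leak
#' clonotype identity into a cell-state score. Clusters with fewer than `k`
#' remaining markers contribute a shorter program with a warning; clusters
#' with none are omitted with a warning.
#'
#' @param markers Marker table from [rank_markers_wilcoxon()].
#' @param k Program size (default 10).
#' @return Named list of character vectors (one ordered gene list per
#'   cluster), of class `signature_programs`.
#' @export
build_programs <- function(markers, k = 10L) {
  if (!nrow(markers)) stopf("marker table is empty")
  assert_scalar_number(k, "k", lower = 1)
  programs <- list()
  for (cl in unique(markers$cluster)) {
    mm <- markers[markers$cluster == cl & markers$significant, , drop = FALSE]
    mm <- mm[!grepl("^TR[ABGD][VDJC]", mm$gene), , drop = FALSE]
    if (!nrow(mm)) {
      warnf("cluster '%s' has no significant markers; program omitted", cl)
      next
    }
    mm <- mm[order(mm$rank_within_cluster), , drop = FALSE]
    if (nrow(mm) < k)
      warnf("cluster '%s' has only %d significant marker(s) (requested %d)",
            cl, nrow(mm), k)
    programs[[cl]] <- utils::head(mm$gene, k)
  }
  structure(programs, class = "signature_programs")
}

#' Rank-based per-cell signature program score
#'
#' Within each cell, genes are ranked by decreasing log expression (ties get
#' the average rank) and ranks are capped at `r_max`; genes absent from the
#' matrix get rank `r_max`. With `n` signature genes of capped ranks `r_i`,
#' the Mann-Whitney-style statistic is `U = sum(r_i) - n(n+1)/2` and the score
#' is `max(0, 1 - U / (n * r_max))`: 1 when the signature occupies the top
#' ranks, near 0 when it sits at or beyond the rank cap. The score depends on
#' expression only through within-cell ranks, so it is invariant under any
#' monotone per-cell transform.
#'
#' @param logmat log1p-normalized genes x cells matrix.
#' @param programs A single character vector of signature genes, or a (named)
#'   list of them (e.g. [build_programs()] output).
#' @param r_max Rank cap (default 1500); must exceed every program size.
#' @return A cells x programs numeric matrix of scores in `[0, 1]` (a single
#'   program still yields a one-column matrix).
#' @export
score_cells <- function(logmat, programs, r_max = 1500L) {
  if (is.character(programs)) programs <- list(program = programs)
  if (!length(programs) || any(!lengths(programs)))
    stopf("programs must be non-empty")
  assert_scalar_number(r_max, "r_max", lower = 1)
  if (any(lengths(programs) >= r_max))
    stopf("program size must be smaller than r_max (%d)", as.integer(r_max))

  # within-cell ranks by decreasing expression, capped at r_max
  rk <- apply(-logmat, 2L, rank)
  rk <- pmin(rk, r_max)

  scores <- vapply(programs, function(genes) {
    present <- genes[genes %in% rownames(logmat)]
    n <- length(genes)
    r_sum <- rep((n - length(present)) * r_max, ncol(logmat))
    if (length(present))
      r_sum <- r_sum + colSums(rk[present, , drop = FALSE])
    u <- r_sum - n * (n + 1) / 2
    pmax(0, 1 - u / (n * r_max))
  }, numeric(ncol(logmat)))
  scores <- matrix(scores, ncol = length(programs),
                   dimnames = list(colnames(logmat), names(programs)))
  scores
}

#' Call gene-positive cells by a read-count threshold
#'
#' A cell is positive for gene X when at least `min_reads` counts of X are
#' detected (default 2, i.e. "more than one read"). In `"any"` mode a cell is
#' positive when any listed gene passes the threshold — the rule used for
#' MHC class II positivity over CD74/HLA-DQ/HLA-DP/HLA-DR. Entries ending in
#' `*` are prefix wildcards expanded against the matrix rownames; genes absent
#' from the matrix are treated as all-zero with a warning. The threshold is
#' applied to the provided count matrix (UMI counts for 10x data).
#'
#' @param counts genes x cells count matrix.
#' @param genes Character vector of gene ids (or `*`-suffixed prefixes).
#' @param min_reads Minimum count (default 2).
#' @param mode `"single"` (exactly one gene) or `"any"`; default `"single"`
#'   for one gene, `"any"` otherwise.
#' @return Named logical vector per cell.
#' @examples
#' m <- matrix(c(2, 1), nrow = 1, dimnames = list("ZNF683", c("c1", "c2")))
#' call_positive_cells(m, "ZNF683")  # c1 TRUE, c2 FALSE
#' @export
call_positive_cells <- function(counts, genes, min_reads = 2L,
                                mode = c("auto", "single", "any")) {
  mode <- match.arg(mode)
  if (!length(genes)) stopf("'genes' must be non-empty")
  assert_scalar_number(min_reads, "min_reads", lower = 1)

  # entries ending in '*' are gene-family prefixes: expand against rownames
  # (an unmatched prefix expands to nothing)
  expanded <- unique(unlist(lapply(genes, function(g) {
    if (!grepl("\\*$", g)) return(g)
    grep(paste0("^", sub("\\*$", "", g)), rownames(counts), value = TRUE,
         fixed = FALSE)
  })))
  if (!length(expanded)) {
    warnf("no listed gene matches the matrix; all cells negative")
    return(stats::setNames(rep(FALSE, ncol(counts)), colnames(counts)))
  }
  if (mode == "auto") mode <- if (length(expanded) == 1L) "single" else "any"
  if (mode == "single" && length(expanded) != 1L)
    stopf("mode 'single' requires exactly one gene after wildcard expansion")

  absent <- setdiff(expanded, rownames(counts))
  if (length(absent))
    warnf("gene(s) absent from the matrix treated as all-zero: %s",
          paste(absent, collapse = ", "))
  present <- intersect(expanded, rownames(counts))
  if (!length(present))
    return(stats::setNames(rep(FALSE, ncol(counts)), colnames(counts)))
  sub <- counts[present, , drop = FALSE]
  pos <- apply(sub >= min_reads, 2L, any)
  stats::setNames(as.logical(pos), colnames(counts))
}
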