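#' Cell-type centroid profiles from annotated single-cell expression
#'
#' The centroid of a cell type is the mean of its cells' log1p-normalized
#' expression, gene by gene — the reference profile used for deconvolution.
#'
#' @param logmat log1p-normalized genes x cells matrix.
#' @param labels Cell-type label per cell (length `ncol(logmat)`); factor
#'   levels with zero cells raise an error naming the type.
#' @return cell-type x gene matrix of mean log expression.
#' @export
compute_centroids <- function(logmat, labels) {
  labels <- as.factor(labels)
  if (length(labels) != ncol(logmat))
    stopf("'labels' must have one entry per cell")
  empty <- levels(labels)[table(labels) == 0L]
  if (length(empty)) stopf("cell type '%s' has no cells", empty[1L])
  centroids <- matrix(0, nrow = nlevels(labels), ncol = nrow(logmat),
                      dimnames = list(levels(labels), rownames(logmat)))
  for (tp in levels(labels))
    centroids[tp, ] <- rowMeans(logmat[, labels == tp, drop = FALSE])
  centroids
}

# objectives for a candidate gene subset: mean pairwise Pearson correlation
# between centroid rows (minimize) and mean pairwise Euclidean distance
# (maximize); constant rows contribute correlation 0
selection_objectives <- function(centroids, idx) {
  sub <- centroids[, idx, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(sub)))
  cc[!is.finite(cc)] <- 0
  up <- upper.tri(cc)
  c(correlation = mean(cc[up]), distance = mean(stats::dist(sub)))
}

# TRUE where a dominates b (both objectives: minimize correlation, maximize
# distance), vectorized over rows of obj against one point
dominates <- function(corr_a, dist_a, corr_b, dist_b) {
  (corr_a <= corr_b & dist_a >= dist_b) &
    (corr_a < corr_b | dist_a > dist_b)
}

pareto_front <- function(corr, dist) {
  n <- length(corr)
  nd <- logical(n)
  for (i in seq_len(n))
    nd[i] <- !any(dominates(corr, dist, corr[i], dist[i]))
  nd
}

#' Multi-objective marker-gene selection for deconvolution
#'
#' Searches for a subset of `n_features` genes over which the cell-type
#' centroid profiles are maximally distinguishable, using a seeded
#' evolutionary search over two objectives: minimize the mean pairwise Pearson
#' correlation between centroid rows and maximize their mean pairwise
#' Euclidean distance. The search is population-based (random initialization,
#' binary tournament selection by Pareto dominance, uniform crossover,
#' per-gene mutation at rate `1/n_candidates`, size repair), evaluating at
#' most `n_solutions` candidate subsets. From the non-dominated front of all
#' evaluated subsets, the member minimizing the correlation objective is
#' returned.
#'
#' @param centroids cell-type x gene matrix, typically restricted to highly
#'   variable genes ([select_hvg()]); at least 2 cell types.
#' @param n_features Subset size (default 400); truncated to the number of
#'   candidate genes with a warning when larger.
#' @param n_solutions Evaluation budget (default 5000).
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @param pop_size Population size (default 100).
#' @return An object of class `marker_selection`: list with `genes` (selected
#'   ids), `correlation`, `distance` (objective values), `front` (objective
#'   matrix of the non-dominated set), `n_evaluated`, `seed`.
#' @export
select_marker_genes <- function(centroids, n_features = 400L,
                                n_solutions = 5000L, seed = 1L,
                                pop_size = 100L) {
  if (nrow(centroids) < 2L) stopf("need at least 2 cell types")
  n_cand <- ncol(centroids)
  if (is.null(colnames(centroids)))
    colnames(centroids) <- sprintf("g%05d", seq_len(n_cand))
  if (n_features > n_cand) {
    warnf("n_features (%d) exceeds the %d candidate genes; using all",
          n_features, n_cand)
    n_features <- n_cand
  }
  set.seed(seed)

  if (n_features == n_cand) {
    obj <- selection_objectives(centroids, seq_len(n_cand))
    return(structure(list(genes = colnames(centroids),
                          correlation = obj[["correlation"]],
                          distance = obj[["distance"]],
                          front = matrix(obj, nrow = 1,
                                         dimnames = list(NULL, names(obj))),
                          n_evaluated = 1L, seed = seed),
                     class = "marker_selection"))
  }

  pop_size <- min(pop_size, n_solutions)
  n_gen <- max(0L, floor(n_solutions / pop_size) - 1L)
  mut_rate <- 1 / n_cand

  repair <- function(members) {
    k <- length(members)
    if (k > n_features) members <- sort(sample(members, n_features))
    else if (k < n_features)
      members <- sort(c(members, sample(setdiff(seq_len(n_cand), members),
                                        n_features - k)))
    members
  }
  pop <- replicate(pop_size, sort(sample.int(n_cand, n_features)),
                   simplify = FALSE)

  arch_sets <- list()
  arch_corr <- numeric(0)
  arch_dist <- numeric(0)

  evaluate <- function(pop) {
    obj <- vapply(pop, function(idx) selection_objectives(centroids, idx),
                  numeric(2))
    arch_sets <<- c(arch_sets, pop)
    arch_corr <<- c(arch_corr, obj[1L, ])
    arch_dist <<- c(arch_dist, obj[2L, ])
    obj
  }

  obj <- evaluate(pop)
  for (gen in seq_len(n_gen)) {
    tournament <- function() {
      ij <- sample.int(pop_size, 2L)
      a <- ij[1L]; b <- ij[2L]
      if (dominates(obj[1L, a], obj[2L, a], obj[1L, b], obj[2L, b])) a
      else if (dominates(obj[1L, b], obj[2L, b], obj[1L, a], obj[2L, a])) b
      else if (obj[1L, a] <= obj[1L, b]) a else b
    }
    offspring <- lapply(seq_len(pop_size - 1L), function(i) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      # uniform crossover on membership vectors
      m1 <- logical(n_cand); m1[p1] <- TRUE
      m2 <- logical(n_cand); m2[p2] <- TRUE
      pick <- stats::runif(n_cand) < 0.5
      child <- which(ifelse(pick, m1, m2))
      flip <- which(stats::runif(n_cand) < mut_rate)
      child <- sort(union(setdiff(child, flip), setdiff(flip, child)))
      repair(child)
    })
    # elitism: carry the current minimum-correlation individual
    elite <- pop[[which.min(obj[1L, ])]]
    pop <- c(list(elite), offspring)
    obj <- evaluate(pop)
  }

  nd <- pareto_front(arch_corr, arch_dist)
  front <- cbind(correlation = arch_corr[nd], distance = arch_dist[nd])
  pick <- which(nd)[which.min(arch_corr[nd])]
  structure(list(genes = colnames(centroids)[arch_sets[[pick]]],
                 correlation = arch_corr[pick],
                 distance = arch_dist[pick],
                 front = front,
                 n_evaluated = length(arch_corr),
                 seed = seed),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf(paste0("marker_selection: %d gene(s); correlation %.4f, ",
                     "distance %.4f (%d subsets evaluated, seed %d)\n"),
              length(x$genes), x$correlation, x$distance, x$n_evaluated,
              x$seed))
  invisible(x)
}

#' Non-negative least-squares deconvolution of bulk expression
#'
#' Estimates cell-type mixture weights per bulk sample by solving
#' `min || A w - b ||_2` subject to `w >= 0`, where the columns of `A` are the
#' cell-type centroid profiles restricted to the selected marker genes
#' (Lawson-Hanson active-set NNLS via [pracma::lsqnonneg()]). Weights are
#' normalized to proportions; an all-zero solution is flagged degenerate. The
#' bulk matrix must be on the same (log) scale as the centroids — use
#' [normalize_counts()]-style log1p CPM units for raw bulk counts.
#'
#' @param bulk genes x samples matrix.
#' @param centroids cell-type x gene matrix ([compute_centroids()]).
#' @param selection Optional `marker_selection` (or character vector of gene
#'   ids) restricting the fit; default: all genes shared by bulk and
#'   centroids.
#' @return An object of class `mixture_estimate`: list with `weights` and
#'   `proportions` (samples x types matrices), `residual_norm`, `degenerate`
#'   (logical per sample), `rank_deficient` (logical), `genes`.
#' @export
nnls_deconvolve <- function(bulk, centroids, selection = NULL) {
  genes <- if (is.null(selection)) colnames(centroids)
           else if (inherits(selection, "marker_selection")) selection$genes
           else as.character(selection)
  missing_b <- setdiff(genes, rownames(bulk))
  missing_c <- setdiff(genes, colnames(centroids))
  if (length(missing_b) || length(missing_c))
    stopf("gene-order mismatch: '%s' absent from %s",
          c(missing_b, missing_c)[1L],
          if (length(missing_b)) "the bulk matrix" else "the centroids")
  n_types <- nrow(centroids)
  if (length(genes) < n_types)
    stopf("need at least as many selected genes (%d) as cell types (%d)",
          length(genes), n_types)

  A <- t(centroids[, genes, drop = FALSE])
  rank_deficient <- qr(A)$rank < n_types
  if (rank_deficient)
    warnf("centroid matrix is rank-deficient on the selected genes")

  samples <- colnames(bulk) %||% sprintf("sample%03d", seq_len(ncol(bulk)))
  weights <- matrix(0, nrow = ncol(bulk), ncol = n_types,
                    dimnames = list(samples, rownames(centroids)))
  resid <- numeric(ncol(bulk))
  for (j in seq_len(ncol(bulk))) {
    fit <- pracma::lsqnonneg(A, bulk[genes, j])
    weights[j, ] <- fit$x
    resid[j] <- sqrt(max(fit$resid.norm, 0))
  }
  tot <- rowSums(weights)
  degenerate <- tot <= 0
  if (any(degenerate))
    warnf("%d sample(s) produced an all-zero weight vector", sum(degenerate))
  proportions <- weights
  proportions[!degenerate, ] <- weights[!degenerate, , drop = FALSE] /
    tot[!degenerate]

  structure(list(weights = weights, proportions = proportions,
                 residual_norm = resid, degenerate = degenerate,
                 rank_deficient = rank_deficient, genes = genes),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("mixture_estimate: %d sample(s) x %d cell type(s) on %d gene(s)\n",
              nrow(x$proportions), ncol(x$proportions), length(x$genes)))
  print(utils::head(round(x$proportions, 3)))
  invisible(x)
}

#' Paired donor-recipient contrast of deconvolved proportions
#'
#' Tests, for one target cell type, whether its estimated proportion differs
#' between recipients and their paired donors (paired t-test by default, or
#' the exact Wilcoxon signed-rank test). With fewer than 3 complete pairs only
#' the mean difference is reported.
#'
#' @param estimates A `mixture_estimate` ([nnls_deconvolve()]) or a samples x
#'   types proportion matrix.
#' @param pairing data.frame with `sample_id`, `pair_id`, `role`.
#' @param target_type Cell type to contrast.
#' @param method `"t"` (paired t-test) or `"signrank"`.
#' @return A list: `target_type`, `n_pairs`, `mean_difference`
#'   (recipient - donor), `statistic`, `p_value`, `method`.
#' @export
contrast_estimates <- function(estimates, pairing, target_type,
                               method = c("t", "signrank")) {
  method <- match.arg(method)
  props <- if (inherits(estimates, "mixture_estimate")) estimates$proportions
           else as.matrix(estimates)
  if (!target_type %in% colnames(props))
    stopf("target type '%s' absent from the estimates", target_type)
  assert_columns(pairing, c("sample_id", "pair_id", "role"), "pairing map")

  pairs <- split(pairing, pairing$pair_id)
  d <- vapply(pairs, function(pp) {
    dn <- pp$sample_id[pp$role == "donor"]
    rc <- pp$sample_id[pp$role == "recipient"]
    if (length(dn) != 1L || length(rc) != 1L) return(NA_real_)
    props[rc, target_type] - props[dn, target_type]
  }, numeric(1))
  d <- d[!is.na(d)]
  if (!length(d)) stopf("no complete donor-recipient pairs found")

  if (length(d) < 3L) {
    warnf("fewer than 3 complete pairs: descriptive output only")
    return(list(target_type = target_type, n_pairs = length(d),
                mean_difference = mean(d), statistic = NA_real_,
                p_value = NA_real_, method = "descriptive"))
  }
  if (stats::sd(d) == 0) {
    # degenerate: all pair differences identical
    return(list(target_type = target_type, n_pairs = length(d),
                mean_difference = mean(d), statistic = 0,
                p_value = if (mean(d) == 0) 1 else 0, method = method))
  }
  ht <- if (method == "t") stats::t.test(d)
        else stats::wilcox.test(d, exact = TRUE)
  list(target_type = target_type, n_pairs = length(d),
       mean_difference = mean(d),
       statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method)
}
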