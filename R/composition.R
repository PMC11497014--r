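#' Per-sample cell-type proportion table
#'
#' Tabulates the fraction of each sample's cells per cell type (absent types
#' get 0). Optionally applies a logit transform for variance stabilization,
#' with a Haldane-style offset of `1/(2 * n_cells_sample)` applied to exact
#' 0/1 entries so the transform stays finite.
#'
#' @param metadata Cell table with `sample_id` (or `subject_id`) and `subset`
#'   columns; `pair_id`, `role`, `group` are carried into the sample map.
#' @param transform `"none"` or `"logit"`.
#' @return An object of class `proportion_table`: list with `props` (samples x
#'   types raw fractions), `values` (analysis scale, transformed if
#'   requested), `samples` (sample map data.frame), `n_cells`, `transform`.
#' @export
cell_type_proportions <- function(metadata, transform = c("none", "logit")) {
  transform <- match.arg(transform)
  if (!"sample_id" %in% names(metadata) && "subject_id" %in% names(metadata))
    metadata$sample_id <- metadata$subject_id
  assert_columns(metadata, c("sample_id", "subset"), "cell metadata")
  metadata <- metadata[!is.na(metadata$subset), , drop = FALSE]
  if (!nrow(metadata)) stopf("no cells with cell-type labels")

  tab <- table(metadata$sample_id, metadata$subset)
  n_cells <- rowSums(tab)
  props <- sweep(unclass(tab), 1L, n_cells, `/`)

  values <- props
  if (transform == "logit") {
    off <- 1 / (2 * n_cells)
    values <- props
    for (i in seq_len(nrow(values))) {
      v <- values[i, ]
      v[v == 0] <- off[i]
      v[v == 1] <- 1 - off[i]
      values[i, ] <- v
    }
    values <- log(values / (1 - values))
  }

  map_cols <- intersect(c("sample_id", "pair_id", "role", "group"),
                        names(metadata))
  samples <- unique(metadata[, map_cols, drop = FALSE])
  samples <- samples[match(rownames(props), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  structure(list(props = props, values = values, samples = samples,
                 n_cells = n_cells, transform = transform),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("proportion_table: %d sample(s) x %d cell type(s), transform=%s\n",
              nrow(x$props), ncol(x$props), x$transform))
  print(utils::head(round(x$props, 3)))
  invisible(x)
}

# method-of-moments empirical-Bayes hyperparameters for variance shrinkage:
# s2 ~ s0^2 * F(df, d0). Relative dispersion r = var(s2)/mean(s2)^2 satisfies
# r = 2 (df + d0 - 2) / (df (d0 - 4)); r * df <= 2 (under-dispersion) maps to
# d0 = Inf (a common variance).
estimate_prior <- function(s2, df) {
  m1 <- mean(s2)
  if (m1 <= 0) return(list(d0 = Inf, s02 = 0))
  r <- stats::var(s2) / m1^2
  if (!is.finite(r) || r * df <= 2) return(list(d0 = Inf, s02 = m1))
  d0 <- (4 * r * df + 2 * df - 4) / (r * df - 2)
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

moderate_variances <- function(s2, df, prior_df = NULL, prior_var = NULL) {
  if (is.null(prior_df)) {
    pr <- estimate_prior(s2, df)
    d0 <- pr$d0
    s02 <- pr$s02
  } else {
    d0 <- prior_df
    s02 <- prior_var %||% (if (is.finite(d0) && d0 > 2)
      mean(s2) * (d0 - 2) / d0 else mean(s2))
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2))
          else (d0 * s02 + df * s2) / (d0 + df)
  list(post_var = post, d0 = d0, s02 = s02, total_df = df + d0)
}

#' Paired moderated test of cell-type composition (recipient vs donor)
#'
#' For each cell type, computes the within-pair differences
#' (recipient - donor) of the proportion table's analysis values, then a
#' moderated one-sample t-test: the per-type variances of the differences are
#' shrunk toward a common prior by the empirical-Bayes construction
#' `s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df)` with hyperparameters
#' `(d0, s0^2)` estimated by method of moments across cell types, and the
#' moderated t `mean(d) / (s_tilde / sqrt(n))` is referred to a t distribution
#' on `df + d0` degrees of freedom. `prior_df = 0` recovers the ordinary
#' paired t-test exactly; `prior_df = Inf` tests against the common prior
#' variance. P-values are BH-adjusted across cell types. With fewer than 3
#' complete pairs the output is descriptive (p not computable).
#'
#' @param props A `proportion_table` ([cell_type_proportions()]), or a samples
#'   x types numeric matrix (then `pairing` is required).
#' @param pairing Optional data.frame (`sample_id`, `pair_id`, `role`)
#'   overriding the table's sample map.
#' @param prior_df Optional prior degrees of freedom `d0` overriding the
#'   method-of-moments estimate (0 = ordinary paired t, Inf = common
#'   variance).
#' @param prior_var Optional prior variance `s0^2` accompanying `prior_df`.
#' @return A data.frame per cell type: mean_difference, ordinary_t,
#'   moderated_t, residual_df, prior_df, prior_var, p_value, adjusted_p; the
#'   number of pairs is the `n_pairs` attribute.
#' @export
paired_moderated_test <- function(props, pairing = NULL, prior_df = NULL,
                                  prior_var = NULL) {
  if (inherits(props, "proportion_table")) {
    values <- props$values
    pairing <- pairing %||% props$samples
  } else values <- as.matrix(props)
  assert_columns(pairing, c("sample_id", "pair_id", "role"), "pairing map")

  pairs <- split(pairing, pairing$pair_id)
  diffs <- do.call(cbind, lapply(pairs, function(pp) {
    d <- pp$sample_id[pp$role == "donor"]
    r <- pp$sample_id[pp$role == "recipient"]
    if (length(d) != 1L || length(r) != 1L) return(NULL)
    as.numeric(values[r, ]) - as.numeric(values[d, ])
  }))
  if (is.null(diffs)) stopf("no complete donor-recipient pairs found")
  rownames(diffs) <- colnames(values)
  n_pairs <- ncol(diffs)

  mean_d <- rowMeans(diffs)
  if (n_pairs < 3L) {
    warnf("fewer than 3 complete pairs (%d): descriptive output only", n_pairs)
    out <- data.frame(cell_type = rownames(diffs), mean_difference = mean_d,
                      ordinary_t = NA_real_, moderated_t = NA_real_,
                      residual_df = n_pairs - 1, prior_df = NA_real_,
                      prior_var = NA_real_, p_value = NA_real_,
                      adjusted_p = NA_real_, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "n_pairs") <- n_pairs
    return(out)
  }

  df <- n_pairs - 1
  s2 <- apply(diffs, 1L, stats::var)
  mod <- moderate_variances(s2, df, prior_df = prior_df,
                            prior_var = prior_var)
  se_ord <- sqrt(s2 / n_pairs)
  se_mod <- sqrt(mod$post_var / n_pairs)
  t_ord <- ifelse(se_ord > 0, mean_d / se_ord, NA_real_)
  t_mod <- ifelse(se_mod > 0, mean_d / se_mod, NA_real_)
  p <- 2 * stats::pt(-abs(t_mod), df = mod$total_df)

  out <- data.frame(cell_type = rownames(diffs), mean_difference = mean_d,
                    ordinary_t = t_ord, moderated_t = t_mod,
                    residual_df = df, prior_df = mod$d0, prior_var = mod$s02,
                    p_value = p, adjusted_p = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Unpaired moderated test of cell-type composition between groups
#'
#' Per cell type, a two-sample t-statistic with pooled variance, with the same
#' empirical-Bayes variance moderation across cell types as
#' [paired_moderated_test()] and BH adjustment across types. With fewer than
#' 2 samples in a group the output is descriptive.
#'
#' @inheritParams paired_moderated_test
#' @param grouping Optional data.frame (`sample_id`, `group`) overriding the
#'   table's sample map.
#' @param groups The two group labels to contrast (first minus second);
#'   default the two labels present.
#' @return A data.frame per cell type: mean_difference, ordinary_t,
#'   moderated_t, residual_df, prior_df, prior_var, p_value, adjusted_p.
#' @export
unpaired_moderated_test <- function(props, grouping = NULL, prior_df = NULL,
                                    prior_var = NULL, groups = NULL) {
  if (inherits(props, "proportion_table")) {
    values <- props$values
    grouping <- grouping %||% props$samples
  } else values <- as.matrix(props)
  assert_columns(grouping, c("sample_id", "group"), "grouping map")
  g <- grouping$group[match(rownames(values), grouping$sample_id)]
  groups <- groups %||% sort(unique(stats::na.omit(g)))
  if (length(groups) != 2L) stopf("exactly two groups are required")
  x <- values[which(g == groups[1L]), , drop = FALSE]
  y <- values[which(g == groups[2L]), , drop = FALSE]
  n1 <- nrow(x)
  n2 <- nrow(y)
  mean_d <- colMeans(x) - colMeans(y)

  if (n1 < 2L || n2 < 2L) {
    warnf("a group has fewer than 2 samples: descriptive output only")
    out <- data.frame(cell_type = colnames(values), mean_difference = mean_d,
                      ordinary_t = NA_real_, moderated_t = NA_real_,
                      residual_df = n1 + n2 - 2, prior_df = NA_real_,
                      prior_var = NA_real_, p_value = NA_real_,
                      adjusted_p = NA_real_, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }

  df <- n1 + n2 - 2
  s2 <- (apply(x, 2L, stats::var) * (n1 - 1) +
           apply(y, 2L, stats::var) * (n2 - 1)) / df
  mod <- moderate_variances(s2, df, prior_df = prior_df,
                            prior_var = prior_var)
  sefac <- sqrt(1 / n1 + 1 / n2)
  t_ord <- ifelse(s2 > 0, mean_d / (sqrt(s2) * sefac), NA_real_)
  t_mod <- ifelse(mod$post_var > 0, mean_d / (sqrt(mod$post_var) * sefac),
                  NA_real_)
  p <- 2 * stats::pt(-abs(t_mod), df = mod$total_df)
  out <- data.frame(cell_type = colnames(values), mean_difference = mean_d,
                    ordinary_t = t_ord, moderated_t = t_mod,
                    residual_df = df, prior_df = mod$d0, prior_var = mod$s02,
                    p_value = p, adjusted_p = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment
#' (`min over k >= i of m * p_(k) / k`, clipped at 1, in the input order);
#' a validated interface to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("'p' must be numeric")
  if (any(p < 0, na.rm = TRUE) || any(p > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")  # NAs (not computable) are passed through
}
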