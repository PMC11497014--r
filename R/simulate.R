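#' Simulation configuration for paired donor-recipient repertoires
#'
#' Builds and validates the parameter set used by [simulate_pair()],
#' [simulate_expression()] and the pipeline's synthetic stage. The generator
#' encodes the two T-cell reconstitution pathways after allogeneic HSCT:
#' *peripheral* cells carry a clonotype sampled from the donor repertoire
#' (homeostatic expansion of transferred mature T cells), *central* cells carry
#' a de novo clonotype absent from the donor pool (thymic output). The two
#' transplant regimes differ only in the per-subset probability of central
#' origin: the haploidentical (`haplo`) regime has strictly more central
#' reconstitution in effector/memory subsets than the matched-sibling (`MSDT`)
#' regime.
#'
#' @param n_donor_clones Number of clones in the donor repertoire.
#' @param zipf_alpha Zipf skew of donor clone sizes (frequency of the rank-i
#'   clone proportional to `i^-zipf_alpha`); 0 is uniform.
#' @param n_donor_cells,n_recipient_cells Cells sampled per subject.
#' @param subsets Named numeric vector of per-subset cell fractions (sums
#'   to 1).
#' @param central_fraction Named list with one numeric vector per regime
#'   (`MSDT`, `haplo`), each giving the probability that a recipient cell of a
#'   given subset is of central (de novo thymic) origin.
#' @param effector_subsets Subsets on which the haplo > MSDT central-fraction
#'   ordering is enforced (the antigen-experienced compartments).
#' @param expansion_bias Named numeric vector (>= 1 for effector/memory):
#'   peripheral draws of subset s use donor clone weights proportional to
#'   `frequency^expansion_bias[s]`, so effector subsets preferentially resample
#'   large donor clones (frequency tempering).
#' @param n_denovo_clones,denovo_zipf_alpha Size and skew of the recipient's
#'   de novo clone pool (thymic output is modelled as broader, i.e. less
#'   skewed, than the mature donor repertoire).
#' @param collision_rate Probability that a de novo clone reuses a donor
#'   clonotype key (shared-by-chance clonotype); 0 makes provenance an exact
#'   oracle.
#' @param n_genes,markers_per_type,marker_log2_fold Expression model: total
#'   genes, dedicated marker genes per cell type, and the log2 fold by which a
#'   marker's mean is raised in its own type.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param libsize_log_mean,libsize_log_sd Log-normal cell library-size factor
#'   parameters.
#' @param seed Default seed recorded in the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_recipient_cells = 500)
#' cfg$central_fraction$haplo
#' @export
sim_config <- function(n_donor_clones = 1000L,
                       zipf_alpha = 1.0,
                       n_donor_cells = 3000L,
                       n_recipient_cells = 3000L,
                       subsets = c(Tnaive = 0.25, Tcm = 0.25,
                                   Tem = 0.25, Teff = 0.25),
                       central_fraction = list(
                         MSDT = c(Tnaive = 0.90, Tcm = 0.50,
                                  Tem = 0.50, Teff = 0.30),
                         haplo = c(Tnaive = 0.95, Tcm = 0.80,
                                   Tem = 0.80, Teff = 0.70)),
                       effector_subsets = c("Tcm", "Tem", "Teff"),
                       expansion_bias = c(Tnaive = 1.0, Tcm = 1.2,
                                          Tem = 1.5, Teff = 2.0),
                       n_denovo_clones = 2000L,
                       denovo_zipf_alpha = 0.5,
                       collision_rate = 0,
                       n_genes = 2000L,
                       markers_per_type = 25L,
                       marker_log2_fold = 2.0,
                       nb_dispersion = 0.3,
                       libsize_log_mean = 0,
                       libsize_log_sd = 0.3,
                       seed = 1L) {
  assert_scalar_number(n_donor_clones, "n_donor_clones", lower = 1)
  assert_scalar_number(zipf_alpha, "zipf_alpha", lower = 0)
  assert_scalar_number(n_donor_cells, "n_donor_cells", lower = 1)
  assert_scalar_number(n_recipient_cells, "n_recipient_cells", lower = 1)
  assert_scalar_number(n_denovo_clones, "n_denovo_clones", lower = 1)
  assert_scalar_number(denovo_zipf_alpha, "denovo_zipf_alpha", lower = 0)
  assert_scalar_number(collision_rate, "collision_rate", lower = 0, upper = 1)
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(markers_per_type, "markers_per_type", lower = 0)
  assert_scalar_number(marker_log2_fold, "marker_log2_fold", lower = 0)
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(libsize_log_sd, "libsize_log_sd", lower = 0)

  if (is.null(names(subsets)) || any(!nzchar(names(subsets))))
    stopf("'subsets' must be a named vector of fractions")
  if (any(subsets < 0) || any(subsets > 1))
    stopf("subset fractions must lie in [0, 1]")
  if (abs(sum(subsets) - 1) > 1e-9)
    stopf("subset fractions must sum to 1 (got %.12g)", sum(subsets))

  for (reg in c("MSDT", "haplo")) {
    cf <- central_fraction[[reg]]
    if (is.null(cf)) stopf("central_fraction must contain regime '%s'", reg)
    missing <- setdiff(names(subsets), names(cf))
    if (length(missing))
      stopf("central_fraction$%s lacks subset '%s'", reg, missing[1L])
    if (any(cf < 0 | cf > 1))
      stopf("central_fraction$%s must lie in [0, 1]", reg)
  }
  missing_bias <- setdiff(names(subsets), names(expansion_bias))
  if (length(missing_bias))
    stopf("expansion_bias lacks subset '%s'", missing_bias[1L])
  if (any(expansion_bias <= 0)) stopf("expansion_bias must be positive")

  eff <- intersect(effector_subsets, names(subsets))
  bad <- eff[central_fraction$haplo[eff] <= central_fraction$MSDT[eff]]
  if (length(bad))
    stopf(paste0("haplo central_fraction must strictly exceed MSDT for ",
                 "effector/memory subset '%s'"), bad[1L])

  cfg <- list(
    n_donor_clones = as.integer(n_donor_clones),
    zipf_alpha = zipf_alpha,
    n_donor_cells = as.integer(n_donor_cells),
    n_recipient_cells = as.integer(n_recipient_cells),
    subsets = subsets,
    central_fraction = central_fraction,
    effector_subsets = eff,
    expansion_bias = expansion_bias,
    n_denovo_clones = as.integer(n_denovo_clones),
    denovo_zipf_alpha = denovo_zipf_alpha,
    collision_rate = collision_rate,
    n_genes = as.integer(n_genes),
    markers_per_type = as.integer(markers_per_type),
    marker_log2_fold = marker_log2_fold,
    nb_dispersion = nb_dispersion,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Zipf clone table on the current RNG stream; keys are canonical paired
# "TRA:<aa>|TRB:<aa>" clonotype keys built from fresh random CDR3aa strings.
make_clone_pool <- function(n_clones, zipf_alpha, avoid = character(0)) {
  freq <- seq_len(n_clones)^(-zipf_alpha)
  freq <- freq / sum(freq)
  cdr3 <- random_cdr3_unique(2L * n_clones, avoid = avoid)
  tra <- cdr3[seq_len(n_clones)]
  trb <- cdr3[n_clones + seq_len(n_clones)]
  data.frame(clone_id = seq_len(n_clones),
             cdr3_tra = tra, cdr3_trb = trb,
             clonotype_key = paste0("TRA:", tra, "|TRB:", trb),
             frequency = freq, stringsAsFactors = FALSE)
}

#' Simulate a donor TCR repertoire with Zipf-distributed clone sizes
#'
#' Clone relative frequencies follow a Zipf law over clone rank,
#' `p_i` proportional to `i^-zipf_alpha`, normalised to sum to 1 — the
#' standard heavy-tailed null for a healthy adult repertoire. Each clone gets
#' fresh random TRA and TRB CDR3 amino-acid sequences (length 8-20, 20-letter
#' alphabet) and the canonical paired clonotype key `TRA:<aa>|TRB:<aa>`.
#'
#' @param n_clones Number of clones (>= 1).
#' @param zipf_alpha Skew parameter (>= 0; 0 gives equal frequencies).
#' @param seed Integer seed.
#' @return A data.frame with columns `clone_id`, `cdr3_tra`, `cdr3_trb`,
#'   `clonotype_key`, `frequency`.
#' @examples
#' simulate_donor_repertoire(3, 1.0, seed = 7)$frequency  # (6/11, 3/11, 2/11)
#' @export
simulate_donor_repertoire <- function(n_clones, zipf_alpha, seed = 1L) {
  if (!is.numeric(n_clones) || length(n_clones) != 1L || n_clones < 1)
    stopf("'n_clones' must be a positive integer")
  if (!is.numeric(zipf_alpha) || length(zipf_alpha) != 1L || zipf_alpha < 0)
    stopf("'zipf_alpha' must be a non-negative number")
  set.seed(seed)
  make_clone_pool(as.integer(n_clones), zipf_alpha)
}

# draw clone ids for recipient peripheral cells, tempering frequencies by the
# subset's expansion bias: weight proportional to frequency^beta
draw_clones <- function(pool, subsets_of_cells, expansion_bias) {
  out <- integer(length(subsets_of_cells))
  for (s in unique(subsets_of_cells)) {
    idx <- which(subsets_of_cells == s)
    w <- pool$frequency^expansion_bias[[s]]
    out[idx] <- sample.int(nrow(pool), length(idx), replace = TRUE,
                           prob = w / sum(w))
  }
  out
}

#' Simulate one paired donor-recipient T-cell sample
#'
#' Donor cells are a multinomial sample of a Zipf donor clone pool. Each
#' recipient cell is, independently per subset, of *central* origin with
#' probability `central_fraction[regime][subset]` — it then carries a de novo
#' clonotype guaranteed absent from the donor pool (unless `collision_rate`
#' injects shared-by-chance keys) — and otherwise of *peripheral* origin,
#' resampling a clonotype carried by the sampled donor cells (the infused
#' graft) with weights tempered by the subset's `expansion_bias` — large donor
#' clones are preferentially re-expanded in effector/memory subsets, the
#' homeostatic-proliferation signature of peripheral reconstitution. Every
#' peripheral clonotype is therefore observable on the donor side, and origin
#' labels are exactly recoverable from the paired repertoires. The hidden origin of every
#' recipient cell is recorded in the returned truth object.
#'
#' @param config A [sim_config()] object.
#' @param regime `"MSDT"` or `"haplo"`.
#' @param seed Integer seed; the output is a pure function of
#'   `(config, regime, seed)`.
#' @param pair_id Identifier stamped on both subjects (default `"P1"`).
#' @return A list with `donor_cells` and `recipient_cells` (data.frames with
#'   barcode, subject_id, pair_id, role, group, subset, cdr3_tra, cdr3_trb,
#'   clonotype_key) and `truth` (list: `origin` — named character vector per
#'   recipient barcode, `clone_id` per recipient barcode, and the donor pool).
#' @export
simulate_pair <- function(config, regime = c("MSDT", "haplo"), seed = 1L,
                          pair_id = "P1") {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  if (identical(regime, c("MSDT", "haplo"))) regime <- "MSDT"
  if (length(regime) != 1L || !regime %in% c("MSDT", "haplo"))
    stopf("unknown regime '%s'", paste(regime, collapse = ","))
  set.seed(seed)

  pool <- make_clone_pool(config$n_donor_clones, config$zipf_alpha)
  subs <- names(config$subsets)

  # donor cells are a multinomial sample of the donor repertoire at its raw
  # clone frequencies; the expansion bias models the recipient's
  # lymphopenia-induced homeostatic proliferation and applies only there
  donor_subset <- sample(subs, config$n_donor_cells, replace = TRUE,
                         prob = config$subsets)
  donor_clone <- sample.int(nrow(pool), config$n_donor_cells, replace = TRUE,
                            prob = pool$frequency)

  recip_subset <- sample(subs, config$n_recipient_cells, replace = TRUE,
                         prob = config$subsets)
  cf <- config$central_fraction[[regime]]
  central <- stats::runif(config$n_recipient_cells) < cf[recip_subset]

  # peripheral recipient cells resample clonotypes carried by the sampled
  # donor cells (the infused graft), so every peripheral clonotype is
  # observable on the donor side and provenance is an exact oracle
  graft <- pool[sort(unique(donor_clone)), , drop = FALSE]
  recip_clone <- rep(NA_integer_, config$n_recipient_cells)
  if (any(!central))
    recip_clone[!central] <- graft$clone_id[
      draw_clones(graft, recip_subset[!central], config$expansion_bias)]

  # central cells draw from a broader de novo pool, rejection-sampled to be
  # collision-free against donor keys (collision_rate reintroduces overlaps)
  denovo <- make_clone_pool(config$n_denovo_clones, config$denovo_zipf_alpha,
                            avoid = c(pool$cdr3_tra, pool$cdr3_trb))
  if (config$collision_rate > 0) {
    n_coll <- stats::rbinom(1L, nrow(denovo), config$collision_rate)
    if (n_coll > 0) {
      hit <- sample.int(nrow(denovo), n_coll)
      src <- sample.int(nrow(pool), n_coll, replace = TRUE)
      denovo$cdr3_tra[hit] <- pool$cdr3_tra[src]
      denovo$cdr3_trb[hit] <- pool$cdr3_trb[src]
      denovo$clonotype_key[hit] <- pool$clonotype_key[src]
    }
  }
  if (any(central)) {
    w <- denovo$frequency
    recip_clone[central] <- sample.int(nrow(denovo), sum(central),
                                       replace = TRUE, prob = w)
  }

  donor_id <- sprintf("%s-D", pair_id)
  recip_id <- sprintf("%s-R", pair_id)
  donor_bc <- sprintf("%s-%05d", donor_id, seq_len(config$n_donor_cells))
  recip_bc <- sprintf("%s-%05d", recip_id, seq_len(config$n_recipient_cells))

  donor_cells <- data.frame(
    barcode = donor_bc, subject_id = donor_id, pair_id = pair_id,
    role = "donor", group = regime, subset = donor_subset,
    cdr3_tra = pool$cdr3_tra[donor_clone],
    cdr3_trb = pool$cdr3_trb[donor_clone],
    clonotype_key = pool$clonotype_key[donor_clone],
    stringsAsFactors = FALSE)

  src <- ifelse(central, "denovo", "donor")
  recip_cells <- data.frame(
    barcode = recip_bc, subject_id = recip_id, pair_id = pair_id,
    role = "recipient", group = regime, subset = recip_subset,
    cdr3_tra = ifelse(central, denovo$cdr3_tra[recip_clone],
                      pool$cdr3_tra[recip_clone]),
    cdr3_trb = ifelse(central, denovo$cdr3_trb[recip_clone],
                      pool$cdr3_trb[recip_clone]),
    clonotype_key = ifelse(central, denovo$clonotype_key[recip_clone],
                           pool$clonotype_key[recip_clone]),
    stringsAsFactors = FALSE)

  origin <- ifelse(central, "central", "peripheral")
  names(origin) <- recip_bc
  clone_id <- paste0(src, ":", recip_clone)
  names(clone_id) <- recip_bc

  list(donor_cells = donor_cells,
       recipient_cells = recip_cells,
       truth = list(origin = origin, clone_id = clone_id,
                    donor_pool = pool, regime = regime, seed = seed))
}

#' Simulate a cell-type-structured single-cell count matrix
#'
#' Counts are negative binomial around per-gene base means scaled by a
#' log-normal per-cell library-size factor. Each cell type owns a dedicated
#' block of `markers_per_type` genes whose mean is multiplied by
#' `2^marker_log2_fold` in cells of that type, giving known ground-truth
#' marker sets for testing marker ranking, signature scoring and
#' deconvolution.
#'
#' @param cells A data.frame with a `subset` column (cell-type label) and a
#'   `barcode` column; e.g. the row-bound output of [simulate_pair()].
#' @param config A [sim_config()] object (expression fields are used).
#' @param seed Integer seed.
#' @return A list with `counts` (genes x cells integer matrix, dimnames set),
#'   `marker_sets` (named list of true marker gene ids per cell type),
#'   `base_mean` (per-gene base mean) and `libsize` (per-cell library factor).
#' @export
simulate_expression <- function(cells, config, seed = 1L) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  if (!all(c("barcode", "subset") %in% names(cells)))
    stopf("'cells' must have 'barcode' and 'subset' columns")
  if (any(is.na(cells$subset)))
    stopf("every cell must have a cell-type label")
  set.seed(seed)

  types <- sort(unique(cells$subset))
  n_types <- length(types)
  n_genes <- config$n_genes
  if (n_types * config$markers_per_type > n_genes)
    stopf("n_genes (%d) is smaller than the %d marker slots required",
          n_genes, n_types * config$markers_per_type)

  genes <- sprintf("G%05d", seq_len(n_genes))
  marker_sets <- stats::setNames(vector("list", n_types), types)
  for (i in seq_len(n_types)) {
    idx <- (i - 1L) * config$markers_per_type + seq_len(config$markers_per_type)
    marker_sets[[i]] <- genes[idx]
  }

  base_mean <- exp(stats::rnorm(n_genes, mean = -0.5, sd = 1))
  # marker genes get a detectable baseline: genes that act as cell-type
  # markers (and hence enter curated signatures) are moderately expressed in
  # real data, not drawn from the same mostly-silent pool as the background
  all_markers <- unlist(marker_sets, use.names = FALSE)
  base_mean[match(all_markers, genes)] <-
    exp(stats::rnorm(length(all_markers), mean = 1.5, sd = 0.5))
  libsize <- exp(stats::rnorm(nrow(cells), config$libsize_log_mean,
                              config$libsize_log_sd))
  fold <- 2^config$marker_log2_fold

  counts <- matrix(0L, nrow = n_genes, ncol = nrow(cells),
                   dimnames = list(genes, cells$barcode))
  type_of <- match(cells$subset, types)
  for (i in seq_len(n_types)) {
    cols <- which(type_of == i)
    if (!length(cols)) next
    mu_g <- base_mean
    midx <- match(marker_sets[[i]], genes)
    mu_g[midx] <- mu_g[midx] * fold
    mu <- outer(mu_g, libsize[cols])
    draw <- if (config$nb_dispersion > 0)
      stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
    else stats::rpois(length(mu), lambda = mu)
    counts[, cols] <- draw
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, marker_sets = marker_sets,
       base_mean = stats::setNames(base_mean, genes),
       libsize = stats::setNames(libsize, cells$barcode))
}

#' Simulate pseudobulk mixtures of reference centroids with known weights
#'
#' Each pseudobulk column is a convex combination of cell-type centroid
#' profiles, `sum_k w_k * centroid_k`, plus additive Gaussian noise truncated
#' at zero; the weights are drawn from a Dirichlet distribution (or supplied
#' explicitly) and returned as ground truth for deconvolution benchmarks.
#'
#' @param centroids Cell-type x gene matrix (e.g. [compute_centroids()]).
#' @param n_mixtures Number of pseudobulk samples.
#' @param dirichlet_alpha Numeric vector of Dirichlet concentration
#'   parameters, one per cell type (recycled if length 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @param weights Optional n_mixtures x n_types matrix of weights overriding
#'   the Dirichlet draw (rows must be non-negative and sum to 1).
#' @return A list with `bulk` (genes x samples matrix) and `weights`
#'   (samples x types matrix of true mixing proportions).
#' @export
simulate_mixtures <- function(centroids, n_mixtures, dirichlet_alpha = 1,
                              noise_sd = 0, seed = 1L, weights = NULL) {
  if (is.null(dim(centroids)) || !nrow(centroids))
    stopf("'centroids' must be a non-empty cell-type x gene matrix")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_types <- nrow(centroids)
  if (length(dirichlet_alpha) == 1L)
    dirichlet_alpha <- rep(dirichlet_alpha, n_types)
  if (length(dirichlet_alpha) != n_types)
    stopf("length of 'dirichlet_alpha' (%d) must equal the number of cell types (%d)",
          length(dirichlet_alpha), n_types)
  set.seed(seed)
  if (is.null(weights)) {
    g <- matrix(stats::rgamma(n_mixtures * n_types,
                              shape = rep(dirichlet_alpha, each = n_mixtures)),
                nrow = n_mixtures)
    weights <- g / rowSums(g)
  } else {
    weights <- as.matrix(weights)
    if (ncol(weights) != n_types || nrow(weights) != n_mixtures)
      stopf("'weights' must be %d x %d", n_mixtures, n_types)
    if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-9))
      stopf("'weights' rows must be non-negative and sum to 1")
  }
  colnames(weights) <- rownames(centroids)
  rownames(weights) <- sprintf("bulk%03d", seq_len(n_mixtures))

  bulk <- t(centroids) %*% t(weights)
  if (noise_sd > 0)
    bulk <- bulk + stats::rnorm(length(bulk), sd = noise_sd)
  bulk <- pmax(bulk, 0)
  colnames(bulk) <- rownames(weights)
  list(bulk = bulk, weights = weights)
}
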