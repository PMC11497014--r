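#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [pipeline_run()]:
#' input/output paths, the analysis thresholds (all of which are named,
#' defaulted fields so any deviation is visible in the run manifest), the
#' seed, and the synthetic-cohort parameters.
#'
#' @param path Optional YAML file whose keys override the defaults (nested
#'   sections `paths`, `thresholds`, `sim`).
#' @param paths Named list: `out_dir` (required for running), and for
#'   non-simulated inputs `contigs`, `counts_prefix`, `metadata`, `bulk`.
#' @param chain_mode Clonotype key mode for [collapse_to_clonotypes()].
#' @param thresholds Named list; defaults: `lfc_min` 0.1, `padj_max` 0.05,
#'   `min_reads` 2, `r_max` 1500, `n_hvg` 2000, `n_features` 400,
#'   `n_solutions` 5000, `top_k` 10, `min_cells` 10.
#' @param seed Integer seed used by every stochastic stage.
#' @param sim Named list of [sim_config()] overrides plus `n_pairs_per_group`
#'   (default 3) and `n_mixtures` (default 20).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, paths = list(), chain_mode = "both",
                            thresholds = list(), seed = 1L, sim = list()) {
  defaults <- list(lfc_min = 0.1, padj_max = 0.05, min_reads = 2L,
                   r_max = 1500L, n_hvg = 2000L, n_features = 400L,
                   n_solutions = 5000L, top_k = 10L, min_cells = 10L)
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    y <- yaml::read_yaml(path)
    paths <- utils::modifyList(y$paths %||% list(), paths)
    thresholds <- utils::modifyList(y$thresholds %||% list(), thresholds)
    sim <- utils::modifyList(y$sim %||% list(), sim)
    chain_mode <- y$chain_mode %||% chain_mode
    seed <- y$seed %||% seed
  }
  thresholds <- utils::modifyList(defaults, thresholds)

  if (!chain_mode %in% c("both", "trb_only", "tra_only"))
    stopf("invalid chain_mode '%s'", chain_mode)
  assert_scalar_number(thresholds$lfc_min, "lfc_min", lower = 0)
  for (nm in c("padj_max", "min_reads", "r_max", "n_hvg", "n_features",
               "n_solutions", "top_k", "min_cells"))
    assert_scalar_number(thresholds[[nm]], nm, lower = 0, strict_lower = TRUE)
  assert_scalar_number(seed, "seed")

  structure(list(paths = paths, chain_mode = chain_mode,
                 thresholds = thresholds, seed = as.integer(seed),
                 sim = sim),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

#' Run pipeline stages on disk
#'
#' Orchestrates the analysis as subcommands sharing one configuration:
#' \describe{
#'   \item{simulate}{writes a synthetic paired cohort (10x-style contig CSV,
#'     MTX counts + sidecars, metadata TSV, pseudobulk TSV, `truth.json`).}
#'   \item{provenance}{contigs -> productive filter -> clonotype collapse ->
#'     consistent/unique classification per pair -> per-subset summary and
#'     group contrast.}
#'   \item{diversity}{per-subject and per-subject-subset Shannon diversity.}
#'   \item{score}{normalization, marker ranking, top-k signature programs,
#'     per-cell program scores.}
#'   \item{compose}{cell-type proportions, paired and unpaired moderated
#'     tests.}
#'   \item{deconvolve}{HVG-restricted centroids, marker-gene selection, NNLS
#'     deconvolution of the bulk table.}
#'   \item{all}{everything above in order (simulating first when no inputs
#'     are configured).}
#' }
#' Every stage logs to stderr and appends to `manifest.json` in the output
#' directory (config, seed, package version, per-output row counts), so each
#' numeric output is reproducible from (inputs, config, seed).
#'
#' @param subcommand One of `"simulate"`, `"provenance"`, `"diversity"`,
#'   `"score"`, `"compose"`, `"deconvolve"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
pipeline_run <- function(subcommand = c("all", "simulate", "provenance",
                                        "diversity", "score", "compose",
                                        "deconvolve"),
                         config = pipeline_config()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stopf("config paths$out_dir is not set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- if (subcommand == "all")
    c("simulate", "provenance", "diversity", "score", "compose", "deconvolve")
  else subcommand
  if (subcommand == "all" && !is.null(config$paths$contigs))
    stages <- setdiff(stages, "simulate")

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("tcrtrace")),
                   chain_mode = config$chain_mode,
                   thresholds = config$thresholds,
                   stages = list())
  for (st in stages) {
    t0 <- Sys.time()
    outputs <- switch(st,
      simulate = stage_simulate(config),
      provenance = stage_provenance(config),
      diversity = stage_diversity(config),
      score = stage_score(config),
      compose = stage_compose(config),
      deconvolve = stage_deconvolve(config))
    manifest$stages[[st]] <- list(
      outputs = outputs,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    log_stage(st, "done in %.1fs", manifest$stages[[st]]$elapsed_s)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# default locations of the simulated inputs inside out_dir
sim_paths <- function(config) {
  od <- config$paths$out_dir
  list(contigs = config$paths$contigs %||% file.path(od, "contigs.csv"),
       metadata = config$paths$metadata %||% file.path(od, "metadata.tsv"),
       counts_prefix = config$paths$counts_prefix %||% file.path(od, "counts"),
       bulk = config$paths$bulk %||% file.path(od, "bulk.tsv"))
}

stage_simulate <- function(config) {
  sp <- sim_paths(config)
  simargs <- config$sim
  n_pairs <- simargs$n_pairs_per_group %||% 3L
  n_mix <- simargs$n_mixtures %||% 20L
  simargs$n_pairs_per_group <- NULL
  simargs$n_mixtures <- NULL
  cfg <- do.call(sim_config, simargs)

  cells <- list()
  origins <- character(0)
  k <- 0L
  for (regime in c("MSDT", "haplo")) for (i in seq_len(n_pairs)) {
    k <- k + 1L
    pr <- simulate_pair(cfg, regime, seed = config$seed + k,
                        pair_id = sprintf("%s%02d", regime, i))
    cells[[k]] <- rbind(pr$donor_cells, pr$recipient_cells)
    origins <- c(origins, pr$truth$origin)
  }
  cells <- do.call(rbind, cells)
  log_stage("simulate", "%d cells across %d pairs", nrow(cells), k)

  expr <- simulate_expression(cells, cfg, seed = config$seed + 1000L)
  logmat <- normalize_counts(expr$counts)
  centroids <- compute_centroids(logmat, cells$subset)
  mix <- simulate_mixtures(centroids, n_mixtures = n_mix,
                           dirichlet_alpha = 1, noise_sd = 0.02,
                           seed = config$seed + 2000L)

  write_contigs_10x(cells, sp$contigs)
  write_cell_metadata(cells, sp$metadata)
  write_counts_mtx(expr$counts, sp$counts_prefix)
  write_bulk_tsv(mix$bulk, sp$bulk)
  write_truth_json(list(origin = as.list(origins),
                        mixture_weights = mix$weights,
                        marker_sets = expr$marker_sets),
                   file.path(config$paths$out_dir, "truth.json"))
  list(contigs = nrow(cells) * 2L, cells = nrow(cells),
       genes = nrow(expr$counts), bulk_samples = ncol(mix$bulk))
}

load_clonotypes <- function(config) {
  sp <- sim_paths(config)
  contigs <- read_contigs(cfg_path_checked(sp$contigs, "contigs"), "tenx_csv")
  metadata <- read_cell_metadata(cfg_path_checked(sp$metadata, "metadata"))
  filtered <- filter_productive(contigs)
  collapse_to_clonotypes(filtered$contigs, config$chain_mode, metadata)
}

cfg_path_checked <- function(p, field) {
  if (!file.exists(p)) stopf("input file for paths$%s not found: %s", field, p)
  p
}

stage_provenance <- function(config) {
  od <- config$paths$out_dir
  cells <- load_clonotypes(config)
  summaries <- list()
  all_cells <- list()
  for (pid in unique(cells$pair_id)) {
    cc <- cells[cells$pair_id == pid, ]
    pair <- classify_clonotypes(cc[cc$role == "donor", ],
                                cc[cc$role == "recipient", ])
    summaries[[pid]] <- provenance_by_subset(
      pair, min_cells = config$thresholds$min_cells)
    all_cells[[pid]] <- pair$cells
  }
  summaries <- do.call(rbind, summaries)
  write_tsv(do.call(rbind, all_cells), file.path(od, "provenance_cells.tsv"))
  write_tsv(summaries, file.path(od, "provenance_summary.tsv"))
  n_contrast <- 0L
  if (length(unique(summaries$group)) == 2L) {
    contrast <- group_provenance_contrast(summaries)
    jsonlite::write_json(contrast, file.path(od, "provenance_contrast.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    n_contrast <- nrow(contrast)
  }
  list(summary_rows = nrow(summaries), contrast_rows = n_contrast)
}

stage_diversity <- function(config) {
  od <- config$paths$out_dir
  cells <- load_clonotypes(config)
  div <- rbind(
    diversity_by_group(cells, "per_sample",
                       min_cells = config$thresholds$min_cells),
    diversity_by_group(cells, "per_sample_subset",
                       min_cells = config$thresholds$min_cells))
  write_tsv(div, file.path(od, "diversity.tsv"))
  list(strata = nrow(div))
}

load_expression <- function(config) {
  sp <- sim_paths(config)
  counts <- read_counts_mtx(sp$counts_prefix)
  metadata <- read_cell_metadata(cfg_path_checked(sp$metadata, "metadata"))
  metadata <- metadata[match(colnames(counts), metadata$barcode), ]
  list(counts = counts, metadata = metadata)
}

stage_score <- function(config) {
  od <- config$paths$out_dir
  th <- config$thresholds
  ex <- load_expression(config)
  logmat <- normalize_counts(ex$counts)
  markers <- rank_markers_wilcoxon(logmat, ex$metadata$subset,
                                   lfc_min = th$lfc_min,
                                   padj_max = th$padj_max)
  programs <- build_programs(markers, k = th$top_k)
  scores <- score_cells(logmat, programs, r_max = min(th$r_max,
                                                      nrow(logmat) - 1L))
  write_tsv(markers, file.path(od, "markers.tsv"))
  jsonlite::write_json(unclass(programs), file.path(od, "programs.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  write_tsv(data.frame(barcode = rownames(scores), scores,
                       check.names = FALSE),
            file.path(od, "scores.tsv"))
  list(markers = sum(markers$significant), programs = length(programs),
       scored_cells = nrow(scores))
}

stage_compose <- function(config) {
  od <- config$paths$out_dir
  sp <- sim_paths(config)
  metadata <- read_cell_metadata(cfg_path_checked(sp$metadata, "metadata"))
  props <- cell_type_proportions(metadata, transform = "logit")
  write_tsv(data.frame(sample_id = rownames(props$props), props$props,
                       check.names = FALSE),
            file.path(od, "proportions.tsv"))
  paired <- paired_moderated_test(props)
  write_tsv(paired, file.path(od, "paired_tests.tsv"))
  n_unpaired <- 0L
  recip <- props$samples$role == "recipient"
  if (length(unique(props$samples$group[recip])) == 2L &&
      all(table(props$samples$group[recip]) >= 2L)) {
    pr <- cell_type_proportions(metadata[metadata$role == "recipient", ],
                                transform = "logit")
    unpaired <- unpaired_moderated_test(pr)
    write_tsv(unpaired, file.path(od, "unpaired_tests.tsv"))
    n_unpaired <- nrow(unpaired)
  }
  list(paired_rows = nrow(paired), unpaired_rows = n_unpaired)
}

stage_deconvolve <- function(config) {
  od <- config$paths$out_dir
  sp <- sim_paths(config)
  th <- config$thresholds
  ex <- load_expression(config)
  bulk <- read_bulk_tsv(cfg_path_checked(sp$bulk, "bulk"))
  logmat <- normalize_counts(ex$counts)
  hvg <- select_hvg(logmat, n = min(th$n_hvg, nrow(logmat)))
  centroids <- compute_centroids(logmat, ex$metadata$subset)
  sel <- select_marker_genes(centroids[, hvg, drop = FALSE],
                             n_features = th$n_features,
                             n_solutions = th$n_solutions,
                             seed = config$seed)
  est <- nnls_deconvolve(bulk, centroids, sel)
  jsonlite::write_json(list(genes = sel$genes,
                            correlation = sel$correlation,
                            distance = sel$distance,
                            n_evaluated = sel$n_evaluated, seed = sel$seed),
                       file.path(od, "marker_selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(data.frame(sample_id = rownames(est$proportions),
                       est$proportions, check.names = FALSE),
            file.path(od, "mixture_estimates.tsv"))
  list(selected_genes = length(sel$genes), samples = nrow(est$proportions))
}
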