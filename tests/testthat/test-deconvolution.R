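# small reference: 10 cell types with dedicated markers
reference_fixture <- function(n_types = 10L, cells_per_type = 60L,
                              n_genes = 600L, seed = 5L) {
  cfg <- sim_config(n_genes = n_genes, markers_per_type = 15L,
                    marker_log2_fold = 2.5, nb_dispersion = 0.2)
  types <- sprintf("T%02d", seq_len(n_types))
  cells <- data.frame(
    barcode = sprintf("c%05d", seq_len(n_types * cells_per_type)),
    subset = rep(types, each = cells_per_type))
  ex <- simulate_expression(cells, cfg, seed = seed)
  logmat <- normalize_counts(ex$counts)
  list(centroids = compute_centroids(logmat, cells$subset),
       logmat = logmat, cells = cells, marker_sets = ex$marker_sets)
}

test_that("centroids are within-type means and invariant to cell order", {
  lg <- matrix(c(1, 3, 2, 2, 5, 5), nrow = 1,
               dimnames = list("g1", sprintf("c%d", 1:6)))
  lab <- c("A", "A", "B", "B", "C", "C")
  cen <- compute_centroids(lg, lab)
  expect_equal(unname(cen[, "g1"]), c(2, 2, 5))

  single <- compute_centroids(lg[, 1, drop = FALSE], "A")
  expect_equal(unname(single["A", ]), 1)

  perm <- sample(6)
  expect_equal(compute_centroids(lg[, perm, drop = FALSE], lab[perm]), cen)

  expect_error(compute_centroids(lg, factor(lab, levels = c("A", "B", "C", "D"))),
               "'D'")
})

test_that("marker selection finds the discriminating subset in a toy problem", {
  centroids <- rbind(t1 = c(g1 = 1, g2 = 0, g3 = 1),
                     t2 = c(g1 = 0, g2 = 1, g3 = 1))
  sel <- select_marker_genes(centroids, n_features = 2, n_solutions = 200,
                             seed = 1)
  expect_setequal(sel$genes, c("g1", "g2"))
  expect_equal(sel$correlation, -1)

  full <- suppressWarnings(
    select_marker_genes(centroids, n_features = 3, n_solutions = 10, seed = 1))
  expect_setequal(full$genes, c("g1", "g2", "g3"))
  expect_equal(full$n_evaluated, 1L)
  expect_warning(select_marker_genes(centroids, n_features = 5), "candidate")
})

test_that("marker selection is seed-deterministic with stable objectives", {
  ref <- reference_fixture()
  hvg <- select_hvg(ref$logmat, n = 200)
  cen <- ref$centroids[, hvg]
  a <- select_marker_genes(cen, n_features = 60, n_solutions = 600, seed = 3)
  b <- select_marker_genes(cen, n_features = 60, n_solutions = 600, seed = 3)
  expect_identical(a$genes, b$genes)
  other <- lapply(4:6, function(s)
    select_marker_genes(cen, n_features = 60, n_solutions = 600, seed = s))
  corr <- c(a$correlation, vapply(other, `[[`, numeric(1), "correlation"))
  expect_lt(max(corr) - min(corr), 0.05)
})

test_that("NNLS recovers noiseless mixtures exactly", {
  ref <- reference_fixture()
  cen <- ref$centroids

  # pure centroid -> unit vector
  pure <- simulate_mixtures(cen, 1, noise_sd = 0, seed = 1,
                            weights = matrix(c(1, rep(0, 9)), nrow = 1))
  est <- nnls_deconvolve(pure$bulk, cen)
  expect_equal(unname(est$proportions[1, ]), c(1, rep(0, 9)),
               tolerance = 1e-8)

  two <- simulate_mixtures(cen, 1, noise_sd = 0, seed = 1,
                           weights = matrix(c(0.3, 0.7, rep(0, 8)), nrow = 1))
  est2 <- nnls_deconvolve(two$bulk, cen)
  expect_equal(unname(est2$proportions[1, 1:2]), c(0.3, 0.7),
               tolerance = 1e-6)

  mix <- simulate_mixtures(cen, 20, dirichlet_alpha = 1, noise_sd = 0,
                           seed = 2)
  est3 <- nnls_deconvolve(mix$bulk, cen)
  expect_lt(max(abs(est3$proportions - mix$weights)), 1e-6)
})

test_that("raw weights are scale-equivariant, proportions scale-invariant", {
  ref <- reference_fixture()
  mix <- simulate_mixtures(ref$centroids, 3, noise_sd = 0.05, seed = 3)
  est <- nnls_deconvolve(mix$bulk, ref$centroids)
  est2 <- nnls_deconvolve(mix$bulk * 2.5, ref$centroids)
  expect_equal(est2$weights, est$weights * 2.5, tolerance = 1e-6)
  expect_equal(est2$proportions, est$proportions, tolerance = 1e-8)
})

test_that("input validation catches mismatches and rank deficiency", {
  cen <- rbind(t1 = c(g1 = 1, g2 = 0), t2 = c(g1 = 0, g2 = 1))
  bulk <- matrix(1, 2, 1, dimnames = list(c("g1", "gX"), "s1"))
  expect_error(nnls_deconvolve(bulk, cen), "g2")
  expect_error(nnls_deconvolve(bulk[1, , drop = FALSE], cen,
                               selection = "g1"), "at least as many")
  dup <- rbind(t1 = c(g1 = 1, g2 = 1), t2 = c(g1 = 1, g2 = 1))
  b2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_warning(est <- nnls_deconvolve(b2, dup), "rank-deficient")
  expect_true(est$rank_deficient)
})

test_that("selected markers do not hurt recovery relative to random subsets", {
  ref <- reference_fixture()
  hvg <- select_hvg(ref$logmat, n = 200)
  cen <- ref$centroids[, hvg]
  rmse <- function(genes, seed) {
    mix <- simulate_mixtures(ref$centroids, 15, dirichlet_alpha = 1,
                             noise_sd = 0.05 * mean(ref$centroids),
                             seed = seed)
    est <- nnls_deconvolve(mix$bulk, ref$centroids, selection = genes)
    sqrt(mean((est$proportions - mix$weights)^2))
  }
  set.seed(20)
  sel_err <- rand_err <- numeric(10)
  for (i in 1:10) {
    sel <- select_marker_genes(cen, n_features = 60, n_solutions = 400,
                               seed = i)
    sel_err[i] <- rmse(sel$genes, seed = 100 + i)
    rand_err[i] <- rmse(sample(hvg, 60), seed = 100 + i)
  }
  expect_lte(mean(sel_err), mean(rand_err))
})

test_that("paired contrasts of estimated proportions behave at the edges", {
  props <- matrix(c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2), ncol = 1,
                  dimnames = list(c("d1", "r1", "d2", "r2", "d3", "r3"), "T01"))
  pairing <- data.frame(sample_id = rownames(props),
                        pair_id = rep(c("p1", "p2", "p3"), each = 2),
                        role = rep(c("donor", "recipient"), 3))
  same <- contrast_estimates(props, pairing, "T01")
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  expect_error(contrast_estimates(props, pairing, "T99"), "absent")

  expect_warning(
    two <- contrast_estimates(props[1:4, , drop = FALSE], pairing[1:4, ],
                              "T01"), "fewer than 3")
  expect_true(is.na(two$p_value))

  shifted <- props
  shifted[c("r1", "r2", "r3"), 1] <- c(0.26, 0.25, 0.24)
  up <- contrast_estimates(shifted, pairing, "T01")
  expect_gt(up$mean_difference, 0)
  expect_lt(up$p_value, 0.05)
})
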