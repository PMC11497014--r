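test_that("library-size normalization hits the target and log1p is exact", {
  m <- matrix(c(1, 1, 2), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "c1"))
  lg <- normalize_counts(m, target = 1e4)
  expect_equal(unname(expm1(lg[, 1])), c(2500, 2500, 5000))
  expect_equal(attr(lg, "normalization_target"), 1e4)

  m2 <- cbind(m, c2 = c(0, 0, 0))
  expect_warning(lg2 <- normalize_counts(m2), "all-zero")
  expect_equal(ncol(lg2), 1L)

  m3 <- rbind(m, g4 = 0)
  expect_true(all(normalize_counts(m3)["g4", ] == 0))
  expect_error(normalize_counts(matrix(-1)), "non-negative")
  expect_error(normalize_counts(matrix(1.5)), "integers")
})

test_that("HVG selection ranks by binned dispersion and recovers inflated genes", {
  set.seed(11)
  n_genes <- 1000L
  n_cells <- 2000L
  mu <- rep(5, n_genes)
  counts <- matrix(rpois(n_genes * n_cells, mu), nrow = n_genes)
  inflated <- sample.int(n_genes, 50)
  # same mean, 8x variance: NB with size = mu / 7
  counts[inflated, ] <- rnbinom(50 * n_cells, size = 5 / 7, mu = 5)
  dimnames(counts) <- list(sprintf("g%04d", 1:n_genes),
                           sprintf("c%04d", 1:n_cells))
  lg <- normalize_counts(counts)
  top <- select_hvg(lg, n = 100)
  recall <- mean(rownames(counts)[inflated] %in% top)
  expect_gte(recall, 0.95)

  # constant genes never precede genes with positive dispersion
  counts2 <- rbind(counts[1:20, ],
                   flat = matrix(3L, 1, n_cells,
                                 dimnames = list("flat", NULL)))
  lg2 <- normalize_counts(counts2)
  expect_false("flat" %in% select_hvg(lg2, n = 20))

  expect_warning(all_genes <- select_hvg(lg2, n = 5000), "available")
  expect_setequal(all_genes, rownames(lg2))
})

test_that("exact rank-sum p-values match exhaustive enumeration (m+n <= 10)", {
  set.seed(13)
  for (m in 1:9) for (n in 1:(10 - m)) {
    if (n < 1) next
    x <- sample(0:3, m, replace = TRUE)   # heavy ties
    y <- sample(0:3, n, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, ranksum_enum_oracle(x, y),
                 tolerance = 1e-12, info = sprintf("ties m=%d n=%d", m, n))
    xu <- rnorm(m)
    yu <- rnorm(n)
    expect_equal(rank_sum_test(xu, yu)$p_value, ranksum_enum_oracle(xu, yu),
                 tolerance = 1e-12, info = sprintf("untied m=%d n=%d", m, n))
    # and, on untied data, the standard exact implementation
    expect_equal(rank_sum_test(xu, yu)$p_value,
                 stats::wilcox.test(xu, yu, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the large-sample rank-sum path tracks wilcox.test", {
  set.seed(14)
  x <- rnorm(40)
  y <- rnorm(60, 0.4)
  ours <- rank_sum_test(x, y)
  expect_false(ours$exact)
  expect_equal(ours$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # with ties
  xt <- sample(0:5, 30, replace = TRUE)
  yt <- sample(0:5, 40, replace = TRUE)
  expect_equal(rank_sum_test(xt, yt)$p_value,
               stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("marker ranking applies the fold-change and adjusted-p gates", {
  # 5 vs 5 cells: complete separation in gene g1 -> exact p = 2/252
  lg <- rbind(g1 = c(rep(1, 5), rep(0, 5)),
              g2 = rep(0.5, 10),                   # identical distributions
              g3 = c(rep(0.55, 5), rep(0.5, 5)))   # tiny fold change
  colnames(lg) <- sprintf("c%02d", 1:10)
  labels <- rep(c("A", "B"), each = 5)
  mk <- rank_markers_wilcoxon(lg, labels)
  a <- mk[mk$cluster == "A", ]
  expect_equal(a$p_value[a$gene == "g1"], 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_true(a$significant[a$gene == "g1"])
  expect_false(a$significant[a$gene == "g2"])
  # g3: p tiny but log2FC = 0.05/ln2 = 0.072 < 0.1 -> gated out
  expect_lt(a$log2_fold_change[a$gene == "g3"], 0.1)
  expect_false(a$significant[a$gene == "g3"])
  expect_equal(sort(a$rank_within_cluster), 1:3)

  expect_error(rank_markers_wilcoxon(lg, rep("A", 10)), "2 clusters")
  expect_warning(
    rank_markers_wilcoxon(cbind(lg, c99 = c(1, 0, 0)),
                          c(labels, "tiny")), "< 2 cells")
})

test_that("signature programs take top-k markers and exclude TCR-locus genes", {
  mk <- data.frame(
    cluster = "A",
    gene = c(paste0("GENE", 1:2), "TRBV9", paste0("GENE", 3:12)),
    log2_fold_change = 1, p_value = 1e-6, adjusted_p = 1e-5,
    significant = TRUE,
    rank_within_cluster = 1:13)
  pg <- build_programs(mk, k = 10)
  expect_length(pg$A, 10L)
  expect_false("TRBV9" %in% pg$A)
  expect_equal(pg$A, c(paste0("GENE", 1:2), paste0("GENE", 3:10)))

  few <- mk[1:4, ]
  expect_warning(pg2 <- build_programs(few, k = 10), "only")
  expect_length(pg2$A, 3L)   # TRBV9 removed from the 4

  one <- build_programs(mk, k = 1)
  expect_equal(one$A, "GENE1")

  none <- mk
  none$significant <- FALSE
  expect_warning(pg3 <- build_programs(none, k = 10), "no significant")
  expect_length(pg3, 0L)
})

test_that("program scores follow the rank-based U-statistic formula", {
  # 10 genes; program genes occupy the top ranks -> score 1
  lg <- matrix(10:1, ncol = 1, dimnames = list(paste0("g", 1:10), "c1"))
  expect_equal(unname(score_cells(lg, paste0("g", 1:3), r_max = 9)[1, 1]), 1)

  # all program genes absent -> capped at r_max: n=10, r_max=1500
  lg2 <- matrix(rnorm(20), ncol = 2,
                dimnames = list(paste0("g", 1:10), c("c1", "c2")))
  expect_warning(
    s <- score_cells(lg2, paste0("absent", 1:10), r_max = 1500),
    NA)  # absent genes are part of the contract, not a warning
  expect_equal(unname(s[, 1]), rep(55 / 15000, 2), tolerance = 1e-12)

  # hand-computed toy: ranks (1, 4, 9), n = 3, r_max = 1500
  vals <- c(100, 50, 40, 30, 20, 10, 5, 4, 3, 2)
  lg3 <- matrix(vals, ncol = 1, dimnames = list(paste0("g", 1:10), "c1"))
  s3 <- score_cells(lg3, c("g1", "g4", "g9"), r_max = 1500)
  expect_equal(unname(s3[1, 1]), 1 - 8 / 4500, tolerance = 1e-12)

  expect_error(score_cells(lg3, paste0("g", 1:10), r_max = 10), "r_max")
})

test_that("scores are bounded and invariant to monotone within-cell transforms", {
  set.seed(15)
  lg <- matrix(rexp(500), nrow = 50,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:10)))
  prog <- list(p1 = sample(rownames(lg), 5), p2 = sample(rownames(lg), 8))
  s <- score_cells(lg, prog, r_max = 40)
  expect_true(all(s >= 0 & s <= 1))
  s_mono <- score_cells(log1p(lg) * 3, prog, r_max = 40)
  expect_equal(s, s_mono, tolerance = 1e-12)
})

test_that("program scores separate cell types at the generator's default fold", {
  types <- sprintf("type%d", 1:5)
  cells <- data.frame(barcode = sprintf("c%04d", 1:1500),
                      subset = rep(types, each = 300))
  cfg <- sim_config(n_genes = 1500L, markers_per_type = 25L)  # fold 2 default
  ex <- simulate_expression(cells, cfg, seed = 17)
  logmat <- normalize_counts(ex$counts)
  programs <- build_programs(rank_markers_wilcoxon(logmat, cells$subset),
                             k = 10)
  scores <- score_cells(logmat, programs, r_max = 1400)
  own <- scores[cbind(seq_len(nrow(scores)),
                      match(cells$subset, colnames(scores)))]
  best_other <- vapply(seq_len(nrow(scores)), function(i)
    max(scores[i, colnames(scores) != cells$subset[i]]), numeric(1))
  expect_gte(mean(own > best_other), 0.95)
})

test_that("positivity calling uses the more-than-one-read rule", {
  counts <- rbind(ZNF683 = c(2, 1, 0),
                  CD74 = c(0, 3, 0),
                  `HLA-DQA1` = c(0, 0, 5),
                  OTHER = c(9, 9, 9))
  colnames(counts) <- c("c1", "c2", "c3")

  zn <- call_positive_cells(counts, "ZNF683")
  expect_equal(unname(zn), c(TRUE, FALSE, FALSE))

  mhc <- call_positive_cells(counts, c("CD74", "HLA-DQ*", "HLA-DP*", "HLA-DR*"))
  expect_equal(unname(mhc), c(FALSE, TRUE, TRUE))

  expect_warning(ab <- call_positive_cells(counts, "MISSING"), "absent")
  expect_false(any(ab))
  expect_error(call_positive_cells(counts, character(0)), "non-empty")
})
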