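meta_fixture <- function() {
  # 4 pairs x (donor, recipient), 3 cell types with a recipient Teff shift
  rows <- list()
  set.seed(3)
  for (p in 1:4) for (role in c("donor", "recipient")) {
    n <- c(Tnaive = 40, Tem = 30, Teff = if (role == "recipient") 50 else 30) +
      sample(0:6, 3, replace = TRUE)
    sid <- sprintf("P%d-%s", p, substr(role, 1, 1))
    rows[[sid]] <- data.frame(
      barcode = sprintf("%s-%03d", sid, seq_len(sum(n))),
      sample_id = sid, pair_id = sprintf("P%d", p), role = role,
      group = if (p <= 2) "haplo" else "MSDT",
      subset = rep(names(n), n))
  }
  do.call(rbind, rows)
}

test_that("proportion tables sum to one and fill absent types with zero", {
  md <- data.frame(sample_id = "s1", subset = c("A", "A", "B", "C"))
  pt <- cell_type_proportions(md)
  expect_equal(unname(pt$props["s1", c("A", "B", "C")]), c(0.5, 0.25, 0.25))

  md2 <- rbind(md, data.frame(sample_id = "s2", subset = c("A", "A")))
  pt2 <- cell_type_proportions(md2)
  expect_equal(unname(pt2$props["s2", "B"]), 0)
  expect_true(all(abs(rowSums(pt2$props) - 1) < 1e-9))

  lt <- cell_type_proportions(md2, transform = "logit")
  expect_true(all(is.finite(lt$values)))
  # Haldane-style offset: 0 entries become 1/(2n) before the logit
  expect_equal(unname(lt$values["s2", "B"]),
               log((1 / 4) / (1 - 1 / 4)), tolerance = 1e-12)
})

test_that("the d0 -> 0 limit recovers the ordinary paired t exactly", {
  vals <- rbind(d1 = c(a = 0, b = 0), r1 = c(a = 1, b = 0),
                d2 = c(a = 0, b = 0), r2 = c(a = 2, b = 1),
                d3 = c(a = 0, b = 0), r3 = c(a = 3, b = 2))
  pairing <- data.frame(sample_id = rownames(vals),
                        pair_id = rep(c("p1", "p2", "p3"), each = 2),
                        role = rep(c("donor", "recipient"), 3))
  res <- paired_moderated_test(vals, pairing, prior_df = 0)
  expect_equal(res$moderated_t[res$cell_type == "a"], 2 / (1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(res$moderated_t[res$cell_type == "a"], 3.4641, tolerance = 1e-4)
  expect_equal(res$moderated_t, res$ordinary_t, tolerance = 1e-12)
  expect_equal(res$residual_df, c(2, 2))
  # p equals the textbook paired t-test p
  expect_equal(res$p_value[res$cell_type == "a"],
               stats::t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
})

test_that("moderation limits behave as designed", {
  set.seed(8)
  vals <- matrix(rnorm(8 * 6), nrow = 8,
                 dimnames = list(sprintf("s%d", 1:8), sprintf("t%d", 1:6)))
  pairing <- data.frame(sample_id = rownames(vals),
                        pair_id = rep(sprintf("p%d", 1:4), each = 2),
                        role = rep(c("donor", "recipient"), 4))
  ord <- paired_moderated_test(vals, pairing, prior_df = 0)
  inf <- paired_moderated_test(vals, pairing, prior_df = Inf)
  mom <- paired_moderated_test(vals, pairing)

  expect_equal(ord$moderated_t, ord$ordinary_t, tolerance = 1e-12)
  # d0 = Inf: every type tested against the common (mean) variance
  diffs <- vals[c(2, 4, 6, 8), ] - vals[c(1, 3, 5, 7), ]
  s2 <- apply(diffs, 2, var)
  t_common <- colMeans(diffs) / sqrt(mean(s2) / 4)
  expect_equal(inf$moderated_t, unname(t_common), tolerance = 1e-12)
  # moderated t lies between the two limits (shrinkage)
  expect_true(all(
    (abs(mom$moderated_t) - pmin(abs(ord$moderated_t), abs(inf$moderated_t)))
    > -1e-9))

  # equal variances: moderation is a no-op
  vals2 <- vals
  d <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(0, 1, 2, 3),
             c(3, 4, 5, 6), c(5, 6, 7, 8), c(7, 8, 9, 10))
  vals2[c(2, 4, 6, 8), ] <- t(d[, 1:4])
  vals2[c(1, 3, 5, 7), ] <- 0
  eq <- paired_moderated_test(vals2, pairing)
  expect_equal(eq$moderated_t, eq$ordinary_t, tolerance = 1e-9)
})

test_that("the moderated construction matches limma given the same prior", {
  skip_if_not_installed("limma")
  set.seed(9)
  vals <- matrix(rnorm(12 * 20, sd = rep(runif(20, 0.5, 2), each = 12)),
                 nrow = 12,
                 dimnames = list(sprintf("s%d", 1:12), sprintf("t%d", 1:20)))
  pairing <- data.frame(sample_id = rownames(vals),
                        pair_id = rep(sprintf("p%d", 1:6), each = 2),
                        role = rep(c("donor", "recipient"), 6))
  diffs <- t(vals[seq(2, 12, 2), ] - vals[seq(1, 12, 2), ])  # types x pairs
  fit <- limma::eBayes(limma::lmFit(diffs, design = matrix(1, 6, 1)))
  idx <- match(rownames(diffs), rownames(diffs))
  # given the same prior pair (d0, s0^2), our moderated t, df and p must
  # reproduce limma's eBayes exactly
  ours <- paired_moderated_test(vals, pairing, prior_df = fit$df.prior,
                                prior_var = fit$s2.prior)
  idx <- match(ours$cell_type, rownames(diffs))
  expect_equal(ours$moderated_t, unname(fit$t[idx, 1]), tolerance = 1e-9)
  expect_equal(ours$p_value, unname(fit$p.value[idx, 1]), tolerance = 1e-9)
  expect_equal(ours$ordinary_t,
               unname(fit$coefficients[idx, 1] / (fit$sigma[idx] / sqrt(6))),
               tolerance = 1e-9)
})

test_that("unpaired moderated test separates groups and respects symmetry", {
  vals <- rbind(h1 = c(a = 0.60, b = 0.30), h2 = c(a = 0.61, b = 0.31),
                h3 = c(a = 0.59, b = 0.32),
                m1 = c(a = 0.20, b = 0.31), m2 = c(a = 0.21, b = 0.30),
                m3 = c(a = 0.19, b = 0.29))
  grouping <- data.frame(sample_id = rownames(vals),
                         group = rep(c("haplo", "MSDT"), each = 3))
  res <- unpaired_moderated_test(vals, grouping, groups = c("haplo", "MSDT"))
  expect_equal(res$cell_type[which.min(res$p_value)], "a")
  expect_lt(res$p_value[res$cell_type == "a"],
            res$p_value[res$cell_type == "b"])
  expect_gt(res$mean_difference[res$cell_type == "a"], 0)

  flipped <- unpaired_moderated_test(vals, grouping,
                                     groups = c("MSDT", "haplo"))
  expect_equal(flipped$moderated_t, -res$moderated_t, tolerance = 1e-12)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-12)

  # single cell type: no shrinkage possible
  one <- unpaired_moderated_test(vals[, "a", drop = FALSE], grouping)
  expect_equal(one$moderated_t, one$ordinary_t, tolerance = 1e-12)

  expect_warning(
    desc <- unpaired_moderated_test(vals[c(1, 4, 5), ], grouping[c(1, 4, 5), ]),
    "fewer than 2")
  expect_true(all(is.na(desc$p_value)))
})

test_that("identical groups yield near-1 p-values", {
  vals <- rbind(h1 = c(a = 0.5, b = 0.5), h2 = c(a = 0.4, b = 0.6),
                h3 = c(a = 0.6, b = 0.4),
                m1 = c(a = 0.5, b = 0.5), m2 = c(a = 0.4, b = 0.6),
                m3 = c(a = 0.6, b = 0.4))
  grouping <- data.frame(sample_id = rownames(vals),
                         group = rep(c("haplo", "MSDT"), each = 3))
  res <- unpaired_moderated_test(vals, grouping)
  expect_true(all(res$p_value > 0.99))
})

test_that("descriptive fallback with too few pairs", {
  vals <- rbind(d1 = c(a = 0.2), r1 = c(a = 0.5),
                d2 = c(a = 0.3), r2 = c(a = 0.4))
  pairing <- data.frame(sample_id = rownames(vals),
                        pair_id = rep(c("p1", "p2"), each = 2),
                        role = rep(c("donor", "recipient"), 2))
  expect_warning(res <- paired_moderated_test(vals, pairing), "fewer than 3")
  expect_true(is.na(res$p_value))
  expect_equal(res$mean_difference, 0.2, tolerance = 1e-12)
})

test_that("the full composition flow runs from metadata to tests", {
  md <- meta_fixture()
  pt <- cell_type_proportions(md, transform = "logit")
  res <- paired_moderated_test(pt)
  expect_equal(res$cell_type[which.min(res$p_value)], "Teff")
  expect_gt(res$mean_difference[res$cell_type == "Teff"], 0)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
})

test_that("BH adjustment equals the step-up brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(1:6, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(diff(sort(adj)[order(order(p))][order(p)]) > -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
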