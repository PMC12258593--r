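test_that("median-of-ratios size factors match the definition and its symmetries", {
  m <- matrix(c(2, 4, 3, 6, 10, 20), 3, 2, byrow = TRUE)
  expect_equal(size_factors_median_of_ratios(m),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical columns -> unit factors
  m2 <- cbind(a = c(5, 8, 2), b = c(5, 8, 2))
  expect_equal(unname(size_factors_median_of_ratios(m2)), c(1, 1))

  # scaling one column scales its factor proportionally (after the
  # geometric-mean-1 rescaling, ratios are preserved)
  m3 <- matrix(rpois(60, 50) + 1, 20, 3)
  sf <- size_factors_median_of_ratios(m3)
  m3b <- m3
  m3b[, 2] <- m3[, 2] * 3
  sfb <- size_factors_median_of_ratios(m3b)
  expect_equal(sfb[2] / sf[2] / (sfb[1] / sf[1]), 3, tolerance = 1e-9)

  # permutation equivariance
  perm <- c(3, 1, 2)
  expect_equal(unname(size_factors_median_of_ratios(m3[, perm])),
               unname(sf[perm]))

  expect_error(size_factors_median_of_ratios(matrix(c(0, 1, 1, 0), 2, 2)),
               "all-positive")
})

test_that("TPM normalizes by length and sums to 1e6 per sample", {
  expect_equal(as.numeric(tpm(matrix(7, 1, 1), 500)), 1e6)
  v <- tpm(matrix(c(100, 100), 2, 1), c(1000, 2000))
  expect_equal(as.numeric(v), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)

  m <- matrix(rpois(50, 30), 10, 5)
  lens <- runif(10, 200, 5000)
  expect_equal(unname(colSums(tpm(m, lens))), rep(1e6, 5), tolerance = 1e-6)

  mz <- cbind(c(3, 4), c(0, 0))
  expect_warning(tz <- tpm(mz, c(100, 100)), "all-zero")
  expect_equal(unname(tz[, 2]), c(0, 0))

  mm <- matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_error(tpm(mm, c(a = 100)), "missing")
})

test_that("batch mean-centering equalizes batch means and is idempotent", {
  x <- matrix(rnorm(40, 5), 4, 10)
  expect_identical(remove_batch(x, rep("b1", 10)), x)

  batch <- rep(c("b1", "b2"), each = 5)
  adj <- remove_batch(x, batch)
  for (g in 1:4) {
    expect_equal(mean(adj[g, 1:5]), mean(adj[g, 6:10]))
    expect_equal(mean(adj[g, ]), mean(x[g, ]))
  }
  # within-batch deviations preserved
  expect_equal(adj[, 1] - adj[, 2], x[, 1] - x[, 2])
  # idempotent
  expect_equal(remove_batch(adj, batch), adj)
  # confounding warning
  expect_warning(remove_batch(x, batch, condition = rep(c("obese", "lean"), each = 5)),
                 "confounded")
})

test_that("raw log2FC has the stated closed form and scale behavior", {
  g <- rep(c("obese", "lean"), each = 3)
  m <- rbind(c(4, 4, 4, 4, 4, 4))
  expect_equal(log2fc(m, g)$log2fc_raw, 0)

  cc <- 0.5
  m2 <- rbind(c(4 * cc, 4 * cc, 4 * cc, cc, cc, cc))
  expect_equal(log2fc(m2, g, pseudocount = cc)$log2fc_raw, log2(2.5),
               tolerance = 1e-12)

  m3 <- matrix(rpois(120, 40) + 1, 20, 6)
  f1 <- log2fc(m3, g, pseudocount = 0)$log2fc_raw
  f2 <- log2fc(2 * m3, g, pseudocount = 0)$log2fc_raw
  expect_equal(f1, f2)
})

test_that("empirical-Bayes shrinkage contracts toward zero, monotonically in se", {
  set.seed(1)
  lfc <- rnorm(50, 0, 1)
  # se = 0 everywhere -> unchanged (tau2 > 0 from the spread)
  expect_equal(shrink_log2fc(lfc, rep(0, 50)), lfc)

  # se^2 = tau^2 -> exactly halved
  v <- var(lfc)
  se <- rep(sqrt(v / 2), 50)    # tau2 = var - mean(se^2) = v/2 = se^2
  expect_equal(shrink_log2fc(lfc, se), lfc / 2, tolerance = 1e-12)

  # contraction and monotonicity among equal-lfc genes with growing se
  lfc2 <- rep(2, 12)
  se2 <- seq(0.1, 1.2, length.out = 12)
  sh <- shrink_log2fc(c(lfc2, rnorm(20)), c(se2, rep(0.5, 20)))[1:12]
  expect_true(all(abs(sh) <= 2))
  expect_true(all(diff(sh) < 0))

  # all-identical lfc -> tau2 = 0 -> all zero
  expect_equal(shrink_log2fc(rep(1.5, 20), rep(0.3, 20)), rep(0, 20))
  expect_error(shrink_log2fc(1:5, rep(0.1, 5)), ">= 10")
})

test_that("NB Wald test returns p = 1 for identical groups and degenerate genes", {
  half <- matrix(rpois(30, 20), 10, 3)
  m <- cbind(half, half)
  g <- rep(c("obese", "lean"), each = 3)
  expect_equal(nb_two_group_test(m, g)$p_value, rep(1, 10))

  m2 <- rbind(rep(7, 8), c(1, 50, 3, 20, 2, 9, 40, 4))
  g2 <- rep(c("obese", "lean"), each = 4)
  p <- nb_two_group_test(m2, g2)$p_value
  expect_equal(p[1], 1)
  expect_true(all(p > 0 & p <= 1))
  expect_error(nb_two_group_test(m2[, 1:3], c("obese", "lean", "lean")),
               "2 replicates")
})

test_that("low-expression rule follows the at-least-half TPM threshold per group", {
  g <- rep(c("obese", "lean"), each = 4)
  t1 <- matrix(0.3, 1, 8)
  expect_false(low_expression_mask(t1, g))
  t2 <- matrix(0.1, 1, 8)
  expect_true(low_expression_mask(t2, g))
  # exactly half the replicates above threshold -> expressed ("at least half")
  thalf <- matrix(c(0.26, 0.26, 0, 0, 0.26, 0.26, 0, 0), 1)
  expect_false(low_expression_mask(thalf, g))
  # expressed in one group only -> kept (on/off genes preserved)
  t4 <- matrix(c(5, 5, 5, 5, 0, 0, 0, 0), 1)
  expect_false(low_expression_mask(t4, g))
})

test_that("DEG rule applies strict thresholds and the expression filter", {
  expect_true(call_degs(0.01, 1.5, FALSE))
  expect_false(call_degs(0.01, 0.9, FALSE))
  expect_false(call_degs(0.05, 2, FALSE))      # boundary: strict
  expect_false(call_degs(0.049, 1.0, FALSE))   # boundary: strict
  expect_false(call_degs(0.01, 1.5, TRUE))
})

test_that("cross-group distances are Euclidean over all obese-lean pairs", {
  e <- cbind(o1 = c(0, 0), l1 = c(3, 4))
  d <- group_distance(e, c("obese", "lean"), already_log = TRUE)
  expect_equal(d, 5)
  e2 <- matrix(rnorm(10), 2, 5)
  d2 <- group_distance(e2, c("obese", "obese", "lean", "lean", "lean"),
                       already_log = TRUE)
  expect_length(d2, 6)
  expect_equal(group_distance(cbind(c(1, 2), c(1, 2)), c("obese", "lean"),
                              already_log = TRUE), 0)
})

test_that("expression_changes ties the stages together coherently", {
  cfg <- tiny_study(n_genes = 120, n_reps = 5)
  sim <- simulate_counts(cfg)
  ch <- expression_changes(sim$counts$pig$counts, sim$counts$pig$samples,
                           sim$lengths$pig)
  expect_equal(nrow(ch), 120)
  expect_true(all(abs(ch$log2fc_shrunk) <= abs(ch$log2fc_raw) + 1e-12))
  expect_true(all(ch$p_value > 0 & ch$p_value <= 1))
  expect_true(all(ch$is_deg[ch$is_low_expr] == FALSE))
  # planted conserved genes with |lfc| = 2 should mostly be DEGs
  tr <- sim$truth
  planted <- tr$true_class == "conserved" & tr$baseline_log2mean > 4
  expect_gt(mean(ch$is_deg[planted]), 0.8)
})
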