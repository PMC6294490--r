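test_that("cohort summaries: mean, SEM and histogram by hand", {
  co <- summarizeCohort(c(10, 20, 30), "demo", bin_width = 10)
  expect_equal(meanDeltaT(co), 20)
  expect_equal(semDeltaT(co), 10 / sqrt(3))  # 5.7735
  expect_equal(nCells(co), 3)
  expect_equal(co@breaks[1], 0)  # anchored at zero
  expect_equal(sum(co@counts), 3)
  expect_equal(summarizeCohort(rep(7, 5))@sem, 0)
  expect_error(summarizeCohort(c(5)), "at least 2")
})

test_that("the {1,2} vs {3,4} permutation p equals the exhaustive 1/3", {
  # oracle: 6 equal-size splits of {1,2,3,4}; |mean diff| >= 2 in 2 of them
  pool <- c(1, 2, 3, 4)
  splits <- combn(4, 2)
  stats <- apply(splits, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  expect_equal(mean(stats >= 2), 1 / 3)
  res <- resamplingTest(c(1, 2), c(3, 4), n_iterations = 1e4, seed = 54)
  se <- sqrt((1 / 3) * (2 / 3) / 1e4)
  expect_lt(abs(pValue(res) - 1 / 3), 3 * se)
})

test_that("the test is symmetric under label swap with the same seed", {
  a <- c(18, 22, 25, 30); b <- c(33, 35, 41)
  p1 <- pValue(resamplingTest(a, b, 1e4, seed = 55))
  p2 <- pValue(resamplingTest(b, a, 1e4, seed = 55))
  expect_identical(p1, p2)
})

test_that("identical constant cohorts give diff 0 and p = 1", {
  res <- resamplingTest(rep(20, 10), rep(20, 12), n_iterations = 1e4,
                        seed = 56)
  expect_identical(res@observed_diff, 0)
  expect_identical(pValue(res), 1)
})

test_that("p is never 0 nor above 1 (add-one correction)", {
  res <- resamplingTest(1:5, 101:105, n_iterations = 1e3, seed = 57)
  expect_gte(pValue(res), 1 / 1001)
  expect_lte(pValue(res), 1)
  expect_error(resamplingTest(1:3, 4:6, n_iterations = 0), "n_iterations")
})

test_that("the bootstrap variant is a valid sensitivity analysis", {
  set.seed(58)
  a <- rnorm(25, 20, 5); b <- rnorm(25, 28, 5)
  pp <- pValue(resamplingTest(a, b, 1e4, seed = 58))
  pb <- pValue(resamplingTest(a, b, 1e4, seed = 58, method = "bootstrap"))
  expect_lt(pp, 0.01)
  expect_lt(pb, 0.01)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov distance < 0.05)", {
  set.seed(101)
  pv <- replicate(1000, {
    a <- rnorm(25, 25, 8); b <- rnorm(25, 25, 8)
    pValue(resamplingTest(a, b, n_iterations = 1e4))
  })
  ks <- max(abs(sort(pv) - (seq_along(pv) / length(pv))))
  expect_lt(ks, 0.05)
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("fold-changes convert delay ratios to rate reductions", {
  ref <- summarizeCohort(rep(c(19, 21), 10), "ref")
  slow <- summarizeCohort(rep(c(39, 41), 10), "slow")
  fc <- foldChange(ref, slow)
  expect_equal(fc$rate_fold_decrease, 2)
  expect_equal(fc$percent_rate_reduction, 50)
  same <- foldChange(ref, ref)
  expect_equal(same$delta_t_ratio, 1)
  expect_equal(same$percent_rate_reduction, 0)
})

test_that("a configured 1.5-fold slowdown is recovered within its bootstrap CI", {
  layout <- nominalLocusLayout()
  e_dt0 <- 30 * eInvSpeed(1.5, 0.25)
  ref <- sampleCellKinetics(layout, scenarioConfig(n_cells = 24, seed = 59))
  tst <- sampleCellKinetics(layout, scenarioConfig(
    n_cells = 25, seed = 60, folded_fraction = 1, pause_mean = 0.5 * e_dt0))
  ci <- bootstrapRatioCI(ref$delta_t_true, tst$delta_t_true, seed = 61)
  expect_gte(1.5, ci["lower"])
  expect_lte(1.5, ci["upper"])
})

test_that("star notation follows the figure-legend thresholds", {
  expect_identical(starSignificance(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("compareCohorts assembles summaries, tests and fold-changes", {
  set.seed(62)
  ev <- list(wt = rnorm(45, 20, 4), g4 = rnorm(25, 40, 8))
  rep_ <- compareCohorts(ev, reference = "wt", n_iterations = 1e4, seed = 62)
  expect_identical(rep_$comparisons$label, "g4")
  expect_lt(rep_$comparisons$p_value, 0.001)
  expect_equal(rep_$comparisons$delta_t_ratio, 2, tolerance = 0.15)
})
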