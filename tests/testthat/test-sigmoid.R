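test_that("exact model data are recovered to numerical precision", {
  t <- 0:179
  y <- sigmoidTraceModel(t, B = 100, A = 100, t_mid = 60, tau = 2)
  f <- fitIntensitySigmoid(t, y)
  expect_true(f@converged)
  expect_lt(abs(tMid(f) - 60), 1e-3)
  expect_equal(plateauFold(f), 2, tolerance = 1e-6)
  expect_equal(f@tau, 2, tolerance = 1e-4)
  expect_gt(f@r_squared, 1 - 1e-10)
})

test_that("mid-rise time is recovered within a frame at 2% noise", {
  set.seed(50)
  errs <- vapply(1:100, function(i) {
    t <- 0:179
    y <- sigmoidTraceModel(t, 3000, 3000, 75, 1.7, 0.002) + rnorm(180, sd = 60)
    f <- fitIntensitySigmoid(t, y)
    if (!f@converged) return(Inf)
    abs(tMid(f) - 75)
  }, 0)
  expect_lt(median(errs), 1)
})

test_that("a flat trace fits with near-zero amplitude and fails QC", {
  set.seed(51)
  t <- 0:179
  y <- 1000 + rnorm(180, sd = 20)
  f <- fitIntensitySigmoid(t, y)
  r <- fitIntensitySigmoid(t, sigmoidTraceModel(t, 1000, 1000, 90, 2),
                           channel = "red")
  ev <- computeDeltaT(f, r)
  flt <- qcFilter(ev)
  expect_identical(nrow(flt$passed), 0L)
  expect_match(flt$failed$qc_reasons, "fold_out_of_range|low_r2")
})

test_that("missing values are tolerated and too-short traces never error", {
  t <- 0:179
  y <- sigmoidTraceModel(t, 100, 100, 60, 2)
  y[sample.int(180, 30)] <- NA
  f <- fitIntensitySigmoid(t, y)
  expect_true(f@converged)
  expect_lt(abs(tMid(f) - 60), 0.1)
  short <- fitIntensitySigmoid(0:4, rnorm(5))
  expect_false(short@converged)
})

test_that("time shifts move t_mid exactly; intensity scaling leaves it fixed", {
  t <- 0:179
  y <- sigmoidTraceModel(t, 200, 200, 80, 2.5, 0.003)
  f0 <- fitIntensitySigmoid(t, y)
  fs <- fitIntensitySigmoid(t + 17, y)
  expect_equal(tMid(fs) - tMid(f0), 17, tolerance = 1e-4)
  fc <- fitIntensitySigmoid(t, 3.7 * y)
  expect_equal(tMid(fc), tMid(f0), tolerance = 1e-4)
  expect_equal(fc@tau, f0@tau, tolerance = 1e-4)
  expect_equal(fc@B / f0@B, 3.7, tolerance = 1e-4)
  expect_equal(fc@A / f0@A, 3.7, tolerance = 1e-4)
})

test_that("fixing the bleach rate at zero matches the free fit on clean data", {
  t <- 0:179
  y <- sigmoidTraceModel(t, 150, 150, 70, 2)  # no bleaching in the data
  free <- fitIntensitySigmoid(t, y)
  fixed <- fitIntensitySigmoid(t, y, fix_bleach = TRUE)
  expect_equal(tMid(free), tMid(fixed), tolerance = 1e-4)
  expect_equal(plateauFold(free), plateauFold(fixed), tolerance = 1e-6)
  expect_lt(free@bleach_rate, 1e-6)
})

test_that("cohort-level delta t is unbiased on simulated traces", {
  set.seed(52)
  layout <- nominalLocusLayout()
  sim <- simulateCohortTraces(layout, scenarioConfig(n_cells = 25, seed = 52),
                              acquisitionConfig())
  fitres <- fitCohortTraces(sim$traces)
  flt <- qcFilter(fitres$events)
  expect_gte(nrow(flt$passed), 20)
  matched <- merge(flt$passed, sim$truth, by = "cell_id")
  expect_lt(abs(mean(matched$delta_t) - mean(matched$delta_t_true)), 0.5)
})
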