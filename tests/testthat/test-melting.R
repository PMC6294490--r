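test_that("the two-state midpoint and monotonicity hold by construction", {
  cv <- simulateMeltingCurve(Tm = 55, dH = 45)
  expect_equal(cv@temps[1], 15)               # starts in the 14-16 degC range
  expect_true(all(diff(cv@temps) == 2))       # 2 degC increments
  expect_equal(twoStateTheta(55, 55, 45), 0.5)
  expect_true(all(diff(cv@signal) < 0))       # strictly decreasing
  expect_error(simulateMeltingCurve(55, -10), "dH")
  expect_error(simulateMeltingCurve(55, 45, temps = c(20, 18, 25)),
               "increasing")
})

test_that("normalization is the identity on already-normalized data", {
  temps <- seq(15, 95, 2)
  y <- twoStateTheta(temps, 55, 150)  # steep: flat plateaus in the quartiles
  norm <- normalizeMelting(temps, y)
  expect_equal(norm@signal, y, tolerance = 1e-6)
})

test_that("normalization inverts any affine transform of the signal", {
  temps <- seq(15, 95, 2)
  set.seed(63)
  y <- twoStateTheta(temps, 50, 40) + rnorm(length(temps), sd = 0.005)
  ref <- normalizeMelting(temps, y)
  aff <- normalizeMelting(temps, 0.37 * y + 1.2)
  expect_equal(aff@signal, ref@signal, tolerance = 1e-9)
})

test_that("normalization guards: too few points, degenerate baselines", {
  expect_error(normalizeMelting(seq(20, 32, 2), rep(1, 7)), "8 points")
  expect_error(normalizeMelting(seq(15, 95, 2), rep(0.5, 41)), "degenerate")
  expect_warning(
    normalizeMelting(seq(15, 95, 2),
                     c(rep(1, 19), 2.5, rep(0, 21))),  # wild outlier
    "outside")
})

test_that("Tm and dH are recovered within 0.3 degC and 5% over 50 seeds", {
  errs <- vapply(1:50, function(s) {
    cv <- simulateMeltingCurve(55, 45, noise_sd = 0.01, seed = s)
    f <- fitTwoStateMelting(cv)
    c(abs(f@Tm - 55), abs(f@dH_vH - 45) / 45)
  }, numeric(2))
  expect_lt(max(errs[1, ]), 0.3)
  expect_lt(max(errs[2, ]), 0.05)
})

test_that("exact model data fit to machine precision with theta(Tm) = 0.5", {
  cv <- simulateMeltingCurve(52, 60)
  f <- fitTwoStateMelting(cv)
  expect_equal(f@Tm, 52, tolerance = 1e-6)
  expect_equal(f@dH_vH, 60, tolerance = 1e-6)
  expect_gt(f@r_squared, 1 - 1e-12)
  expect_equal(foldedFraction(f, f@Tm), 0.5)
  expect_equal(f@dS_vH, f@dH_vH / (f@Tm + 273.15))
})

test_that("fitting is consistent under a uniform temperature offset", {
  base <- fitTwoStateMelting(simulateMeltingCurve(50, 45))
  shifted <- fitTwoStateMelting(
    simulateMeltingCurve(60, 45, temps = seq(25, 105, 2)))
  expect_equal(shifted@Tm - base@Tm, 10, tolerance = 1e-4)
  expect_equal(shifted@dH_vH, base@dH_vH, tolerance = 1e-4)
})

test_that("a refolding-type (increasing) curve is flagged non-standard", {
  temps <- seq(15, 95, 2)
  cv <- new("MeltingCurve", temps = temps,
            signal = 1 - twoStateTheta(temps, 55, 45), label = "refold")
  f <- fitTwoStateMelting(cv)
  expect_true(f@converged)
  expect_lt(f@dH_vH, 0)
  expect_true("non_standard_increasing" %in% f@flags)
  th <- foldedFraction(f, temps)
  expect_true(all(diff(th) > 0))
})

test_that("an unbracketed transition is diagnosed, not fitted", {
  cv <- simulateMeltingCurve(90, 45, temps = seq(15, 55, 2))
  f <- fitTwoStateMelting(cv)
  expect_false(f@converged)
  expect_true("transition_not_bracketed" %in% f@flags)
})

test_that("residual baselines can be co-fitted", {
  temps <- seq(15, 95, 2)
  y <- 0.02 + 0.0005 * temps +
    (0.98 - 0.001 * temps - 0.02 - 0.0005 * temps) *
      twoStateTheta(temps, 55, 45)
  f <- fitTwoStateMelting(new("MeltingCurve", temps = temps, signal = y,
                              label = "bl"), baselines = TRUE)
  expect_equal(f@Tm, 55, tolerance = 0.05)
  expect_equal(f@dH_vH, 45, tolerance = 0.5)
})
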