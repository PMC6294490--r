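test_that("all signal in the full-length window gives fraction 1", {
  pos <- seq(0, 100, length.out = 501)
  prof <- 1000 * dnorm(pos, 85, 2)
  lane <- gelLaneProfile(pos, prof, gelLaneGeometry()$band_windows)
  expect_equal(as.numeric(quantifyFullLengthFraction(lane)), 1)
})

test_that("equal stall and full-length areas give fraction 0.5", {
  pos <- seq(0, 100, length.out = 501)
  prof <- 500 * dnorm(pos, 55, 2) + 500 * dnorm(pos, 85, 2)
  lane <- gelLaneProfile(pos, prof, gelLaneGeometry()$band_windows)
  expect_equal(as.numeric(quantifyFullLengthFraction(lane)), 0.5,
               tolerance = 1e-3)
})

test_that("a configured 30/70 split is recovered within 1%", {
  lanes <- simulateGelTimecourse(k_synth = -log(0.7), times = 1,
                                 noise_sd = 0)
  expect_equal(attr(lanes, "true_fraction"), 0.3)
  f <- quantifyFullLengthFraction(lanes[[1]])
  expect_equal(as.numeric(f), 0.3, tolerance = 0.01)
  # oracle: direct trapezoidal integration of the noiseless band profile
  g <- gelLaneGeometry()
  direct_full <- pracma::trapz(g$positions, 0.3 * g$total_area *
                                 dnorm(g$positions, g$full_pos, g$band_sigma))
  direct_stall <- pracma::trapz(g$positions, 0.7 * g$total_area *
                                  dnorm(g$positions, g$stall_pos, g$band_sigma))
  expect_equal(direct_full / (direct_full + direct_stall), 0.3,
               tolerance = 1e-6)
})

test_that("window fractions sum to one and the primer option widens the denominator", {
  lanes <- simulateGelTimecourse(0.2, times = 5, noise_sd = 0)
  f <- quantifyFullLengthFraction(lanes[[1]])
  expect_equal(sum(attr(f, "fractions")), 1, tolerance = 1e-6)
  f_all <- quantifyFullLengthFraction(lanes[[1]], include_primer = TRUE)
  expect_equal(sum(attr(f_all, "fractions")), 1, tolerance = 1e-6)
  expect_lt(as.numeric(f_all), as.numeric(f))  # primer dilutes the fraction
})

test_that("no synthesis means no full-length product at any time", {
  lanes <- simulateGelTimecourse(0, times = c(1, 5, 10), noise_sd = 0)
  expect_equal(attr(lanes, "true_fraction"), c(0, 0, 0))
  fr <- quantifyGelTimecourse(lanes)$full_length_fraction
  expect_true(all(fr < 0.01))
})

test_that("synthesis saturates at f_max for long times", {
  lanes <- simulateGelTimecourse(0.5, times = c(1, 2, 4, 8, 30),
                                 noise_sd = 0)
  fr <- quantifyGelTimecourse(lanes)
  expect_equal(fr$full_length_fraction[5], 1, tolerance = 0.01)
})

test_that("quantified time courses are non-decreasing in time", {
  lanes <- simulateGelTimecourse(0.25, times = c(0.5, 1, 2, 4, 6, 10),
                                 seed = 64)
  fr <- quantifyGelTimecourse(lanes)$full_length_fraction
  expect_true(all(diff(fr) >= 0))
})

test_that("degenerate inputs are refused", {
  pos <- seq(0, 100, length.out = 201)
  lane <- gelLaneProfile(pos, rep(5, 201),
                         list(full_length = c(40, 60), stall = c(50, 70)))
  expect_error(quantifyFullLengthFraction(lane), "overlap")
  flat <- gelLaneProfile(pos, rep(5, 201),
                         list(full_length = c(40, 60), stall = c(65, 85)))
  expect_error(quantifyFullLengthFraction(flat), "area")
  nofl <- gelLaneProfile(pos, rep(5, 201), list(stall = c(65, 85)))
  expect_error(quantifyFullLengthFraction(nofl), "full_length")
})

test_that("negative corrected intensities are recorded, never clipped away", {
  set.seed(65)
  lanes <- simulateGelTimecourse(0.3, times = 2, noise_sd = 4)
  f <- quantifyFullLengthFraction(lanes[[1]])
  expect_gt(attr(f, "n_clipped"), 0)
  expect_true(as.numeric(f) >= 0 && as.numeric(f) <= 1)
})
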