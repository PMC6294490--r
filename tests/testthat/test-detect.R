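test_that("pure-noise volumes yield no detections in >= 99% of fields", {
  set.seed(42)
  n_nonempty <- sum(vapply(1:100, function(i) {
    vol <- array(rnorm(12 * 32 * 32, mean = 100, sd = 10), c(12, 32, 32))
    nrow(detectSpots(vol, VOX, k_sigma = 5)) > 0
  }, TRUE))
  expect_lte(n_nonempty, 1)
})

test_that("a single SNR-10 spot is found once, within a voxel of truth", {
  set.seed(43)
  center <- c(4.2, 2.3, 2.7)
  vol <- makeSpotVolume(c(12, 40, 40), rbind(center), snr = 10)
  det <- detectSpots(vol, VOX)
  expect_identical(nrow(det), 1L)
  # oracle: the argmax of the noiseless render
  clean <- renderSpotVolume(c(12, 40, 40), VOX, center, amplitude = 1000)
  am <- which(clean == max(clean), arr.ind = TRUE)[1, ] - 1
  expect_lt(abs(det$y - am[2]), 1)
  expect_lt(abs(det$x - am[3]), 1)
  expect_lt(abs(det$z - am[1]), 1)
})

test_that("two well-separated spots give exactly two detections", {
  set.seed(44)
  centers <- rbind(c(4.2, 1.6, 1.6), c(4.2, 1.6, 1.6 + 10 * VOX[3]))
  vol <- makeSpotVolume(c(12, 36, 36), centers, snr = 10)
  det <- detectSpots(vol, VOX)
  expect_identical(nrow(det), 2L)
})

test_that("recall >= 0.95 and sub-voxel xy localization at SNR 8", {
  set.seed(45)
  found <- 0; total <- 0; errs <- numeric()
  for (v in 1:50) {
    dims <- c(12, 48, 48)
    repeat {
      yx <- matrix(runif(8, 0.8, 4.3), 4, 2)
      d <- as.matrix(dist(yx)); diag(d) <- Inf
      if (min(d) > 1.5) break
    }
    centers <- cbind(runif(4, 3.0, 5.4), yx)
    vol <- makeSpotVolume(dims, centers, snr = 8)
    det <- detectSpots(vol, VOX)
    total <- total + 4
    for (i in 1:4) {
      dd <- sqrt((det$y_um - centers[i, 2])^2 + (det$x_um - centers[i, 3])^2)
      if (length(dd) && min(dd) < 3 * VOX[3]) {
        found <- found + 1
        errs <- c(errs, min(dd) / VOX[3])
      }
    }
  }
  expect_gte(found / total, 0.95)
  expect_lt(mean(errs), 1)
  expect_gte(total, 200)
})

test_that("detection requires the voxel anisotropy", {
  vol <- array(0, c(4, 8, 8))
  expect_error(detectSpots(vol), "voxel_size")
  expect_error(detectSpots(vol, voxel_size = c(1, 1)), "voxel_size")
})

test_that("sister foci within the merge radius collapse to one detection", {
  set.seed(46)
  centers <- rbind(c(4.2, 2.1, 2.0), c(4.2, 2.1, 2.0 + 0.3))  # 0.3 um apart
  vol <- makeSpotVolume(c(12, 40, 40), centers, snr = 12)
  det <- detectSpots(vol, VOX, merge_radius = 0.5)
  expect_identical(nrow(det), 1L)
})

test_that("integrated intensity matches direct arithmetic and is linear", {
  dims <- c(12, 40, 40)
  center <- c(4.2, 2.1, 2.1)
  b <- 50
  vol1 <- renderSpotVolume(dims, VOX, center, amplitude = 2000,
                           background = b)
  m1 <- measureSpotIntensity(vol1, center, VOX)
  expect_false(m1$clipped)
  # oracle: direct core sum minus background times core size, via an
  # independently constructed ellipsoid mask
  idx <- as.matrix(expand.grid(z = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               x = 0:(dims[3] - 1)))
  um <- sweep(idx + 0.5, 2, VOX, `*`)
  dn <- sqrt(((um[, 1] - center[1]) / 3)^2 + (um[, 2] - center[2])^2 +
             (um[, 3] - center[3])^2)
  core <- dn <= 0.5
  oracle <- sum(vol1[idx[core, , drop = FALSE] + 1]) - b * sum(core)
  expect_equal(m1$intensity, oracle, tolerance = 1e-9)
  # most of the spot lies in the core
  expect_gt(m1$intensity / 2000, 0.9)
  # doubling the amplitude doubles the background-subtracted measurement
  vol2 <- renderSpotVolume(dims, VOX, center, amplitude = 4000,
                           background = b)
  m2 <- measureSpotIntensity(vol2, center, VOX)
  expect_equal(m2$intensity / m1$intensity, 2, tolerance = 0.01)
})

test_that("an all-zero volume measures zero intensity", {
  m <- measureSpotIntensity(array(0, c(12, 30, 30)), c(4.2, 1.5, 1.5), VOX)
  expect_identical(m$intensity, 0)
})

test_that("a background shell clipped by the edge flags the measurement", {
  vol <- array(10, c(12, 30, 30))
  m <- measureSpotIntensity(vol, c(4.2, 0.2, 0.2), VOX)
  expect_true(m$clipped)
})

test_that("per-frame detection is stateless in processing order", {
  set.seed(47)
  vols <- lapply(1:3, function(i)
    makeSpotVolume(c(12, 32, 32), rbind(c(4.2, 1.7, 1.7)), snr = 10))
  fwd <- lapply(vols, detectSpots, voxel_size = VOX)
  rev_ <- lapply(rev(vols), detectSpots, voxel_size = VOX)
  expect_equal(fwd, rev(rev_))
})
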