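test_that("a stationary spot yields one gapless track", {
  det <- data.frame(frame = 1:5, z_um = 4, y_um = 2, x_um = 2, intensity = 10)
  tracks <- linkTracks(det)
  expect_length(tracks, 1)
  expect_identical(nrow(tracks[[1]]@detections), 5L)
  expect_length(tracks[[1]]@gaps, 0)
})

test_that("a single missing frame is bridged and recorded as a gap", {
  det <- data.frame(frame = c(1, 2, 4, 5), z_um = 4, y_um = 2, x_um = 2,
                    intensity = 10)
  tracks <- linkTracks(det, max_gap = 1)
  expect_length(tracks, 1)
  expect_identical(tracks[[1]]@gaps, 3)
})

test_that("a gap longer than max_gap splits the track", {
  det <- data.frame(frame = c(1, 2, 6, 7), z_um = 4, y_um = 2, x_um = 2,
                    intensity = 10)
  tracks <- linkTracks(det, max_gap = 2)
  expect_length(tracks, 2)
})

test_that("displacements beyond the limit start new tracks", {
  det <- data.frame(frame = 1:2, z_um = 4, y_um = c(1, 4), x_um = 2,
                    intensity = 10)
  tracks <- linkTracks(det, max_displacement = 0.8)
  expect_length(tracks, 2)
})

test_that("greedy linking equals brute-force minimal matching on small sets", {
  set.seed(48)
  for (rep in 1:50) {
    n <- sample(1:3, 1)
    repeat {  # spots well separated relative to their motion
      prev <- cbind(runif(n, 3, 6), runif(n, 1, 6), runif(n, 1, 6))
      if (n == 1) break
      d <- as.matrix(dist(prev)); diag(d) <- Inf
      if (min(d) > 1.2) break
    }
    nxt <- prev + matrix(rnorm(3 * n, sd = 0.1), n, 3)
    expect_identical(greedyAssign(prev, nxt, 0.8),
                     bruteForceAssign(prev, nxt, 0.8))
  }
})

test_that("converging spots keep their identities", {
  # two spots approach each other; step size far below their spacing
  prev <- rbind(c(4, 2.0, 2.0), c(4, 3.6, 2.0))
  nxt <- rbind(c(4, 2.2, 2.0), c(4, 3.4, 2.0))
  expect_identical(greedyAssign(prev, nxt, 0.8), c(1, 2))
  expect_identical(bruteForceAssign(prev, nxt, 0.8), c(1, 2))
})

test_that("close green/red tracks pair; distant ones are reported unpaired", {
  mk <- function(y, ch) new("FocusTrack", channel = ch,
    detections = data.frame(frame = 1:12, z_um = 4, y_um = y, x_um = 2,
                            intensity = 10, response = 1),
    gaps = numeric())
  near <- assembleCellTraces(list(mk(2.0, "green")), list(mk(2.5, "red")),
                             times = 0:11, pairing_radius = 2)
  expect_length(near$traces, 1)
  expect_identical(nrow(near$unpaired), 0L)
  far <- assembleCellTraces(list(mk(2.0, "green")), list(mk(7.0, "red")),
                            times = 0:11, pairing_radius = 2)
  expect_length(far$traces, 0)
  expect_identical(nrow(far$unpaired), 2L)
})

test_that("gap frames stay missing in assembled traces (no interpolation)", {
  g <- new("FocusTrack", channel = "green",
           detections = data.frame(frame = c(1:6, 8:12), z_um = 4, y_um = 2,
                                   x_um = 2, intensity = 10, response = 1),
           gaps = 7)
  r <- new("FocusTrack", channel = "red",
           detections = data.frame(frame = 1:12, z_um = 4, y_um = 2.4,
                                   x_um = 2, intensity = 20, response = 1),
           gaps = numeric())
  res <- assembleCellTraces(list(g), list(r), times = 0:11,
                            pairing_radius = 2, min_length = 5)
  expect_true(is.na(res$traces[[1]]@intensity_green[7]))
  expect_false(anyNA(res$traces[[1]]@intensity_red))
})

test_that("measured traces correlate with their rendered time courses (r >= 0.95)", {
  layout <- nominalLocusLayout()
  acq <- acquisitionConfig(n_frames = 50, n_y = 72, n_x = 72)
  sc <- scenarioConfig(n_cells = 4, seed = 66, firing_time_mean = 15,
                       firing_time_sd = 3)
  mv <- simulateReplicationMovie(layout, sc, acq, seed = 66)
  an <- analyzeMovie(mv)
  expect_length(an$traces, 4)
  m <- matchTracesToTruth(an$positions, mv@spots)
  times <- (seq_len(acq@n_frames) - 1) * acq@frame_interval
  tau <- acq@rise_time / 4
  for (k in seq_along(an$traces)) {
    tr <- an$traces[[k]]
    truth <- mv@truth[mv@truth$cell_id == m$truth_id[k], ]
    for (ch in c("green", "red")) {
      t_rep <- if (ch == "green") truth$t_rep_array1 else truth$t_rep_array2
      model <- sigmoidTraceModel(times, acq@spot_amplitude,
                                 acq@spot_amplitude, t_rep, tau,
                                 acq@bleach_rate)
      r <- cor(traceIntensity(tr, ch), model, use = "complete.obs")
      expect_gte(r, 0.95)
    }
  }
})

test_that("a simulated 10-cell movie yields 10 traces matching ground truth", {
  layout <- nominalLocusLayout()
  acq <- acquisitionConfig(n_frames = 15, n_y = 96, n_x = 96)
  sc <- scenarioConfig(n_cells = 10, seed = 49, firing_time_mean = 60)
  mv <- simulateReplicationMovie(layout, sc, acq, seed = 49)
  an <- analyzeMovie(mv)
  expect_length(an$traces, 10)
  m <- matchTracesToTruth(an$positions, mv@spots)
  expect_false(anyNA(m$truth_id))
  expect_identical(sort(m$truth_id), sort(mv@truth$cell_id))
})
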