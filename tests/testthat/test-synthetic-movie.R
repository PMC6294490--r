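small_acq <- function(...) acquisitionConfig(n_frames = 6, n_y = 48,
                                             n_x = 48, ...)

test_that("movies have the default 12 z-sections and 2 channels", {
  mv <- renderMovie(sampleCellKinetics(nominalLocusLayout(),
                                       scenarioConfig(n_cells = 1, seed = 1)),
                    nominalLocusLayout(), small_acq(), seed = 1)
  d <- dim(mv@data)
  expect_identical(d[2:3], c(2L, 12L))
  expect_true(all(mv@data >= 0))
  expect_identical(mv@metadata@z_step, 0.7)
  expect_identical(mv@metadata@frame_interval, 1)
})

test_that("an empty field is background plus noise only", {
  acq <- small_acq(background_level = 100, read_noise_sd = 5)
  mv <- renderMovie(data.frame(), nominalLocusLayout(), acq, seed = 2)
  x <- as.numeric(mv@data)
  expect_equal(mean(x), 100, tolerance = 0.01)
  # Poisson + read noise variance, slightly shrunk by clamping at zero
  expect_equal(sd(x), sqrt(100 + 25), tolerance = 0.05)
})

test_that("a noiseless rendered spot integrates to its amplitude", {
  vol <- renderSpotVolume(c(12, 40, 40), VOX, c(4.2, 2.1, 2.1),
                          amplitude = 3000)
  expect_equal(sum(vol), 3000, tolerance = 0.005)
})

test_that("movie rendering is seed-reproducible", {
  gt <- sampleCellKinetics(nominalLocusLayout(),
                           scenarioConfig(n_cells = 2, seed = 3))
  a <- renderMovie(gt, nominalLocusLayout(), small_acq(), seed = 9)
  b <- renderMovie(gt, nominalLocusLayout(), small_acq(), seed = 9)
  expect_identical(a@data, b@data)
  c_ <- renderMovie(gt, nominalLocusLayout(), small_acq(), seed = 10)
  expect_false(identical(a@data, c_@data))
})

test_that("overfull fields are refused rather than clipping spots", {
  expect_error(renderMovie(sampleCellKinetics(
    nominalLocusLayout(), scenarioConfig(n_cells = 200, seed = 1)),
    nominalLocusLayout(), small_acq(), seed = 1), "field|outside")
})

test_that("movies round-trip through multi-page TIFF with metadata", {
  gt <- sampleCellKinetics(nominalLocusLayout(),
                           scenarioConfig(n_cells = 1, seed = 4))
  acq <- acquisitionConfig(n_frames = 3, n_y = 32, n_x = 32)
  mv <- renderMovie(gt, nominalLocusLayout(), acq, seed = 4)
  path <- file.path(tempdir(), "movie.tif")
  writeMovieTIFF(mv, path)
  back <- readMovieTIFF(path)
  expect_identical(dim(back@data), dim(mv@data))
  expect_equal(back@data, mv@data, tolerance = 1e-6)
  expect_equal(back@metadata@pixel_size, acq@pixel_size)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("configs round-trip through YAML", {
  p <- file.path(tempdir(), "scenario.yaml")
  yaml::write_yaml(list(label = "g4", fork_speed_mean = 1.2,
                        pause_mean = 12, folded_fraction = 0.8,
                        n_cells = 10), p)
  sc <- scenarioFromYAML(p)
  expect_identical(sc@label, "g4")
  expect_identical(sc@pause_mean, 12)
  unlink(p)
})
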