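# Synthetic movie rendering: each cell contributes one 3D Gaussian focus per
# channel whose integrated intensity follows the bleached logistic step of
# renderTrace(); the field has a uniform background, Poisson shot noise and
# Gaussian read noise, and each cell performs a small common random walk
# (drift). Whole-cell morphology is deliberately not modelled.

# add an integrated-amplitude 3D Gaussian to a (nz, ny, nx) volume in place
addSpot <- function(vol, center_um, amplitude, voxel_size, sigma_xy, sigma_z) {
  dims <- dim(vol)
  sig_um <- c(sigma_z, sigma_xy, sigma_xy)
  idx <- vector("list", 3)
  w <- vector("list", 3)
  for (a in 1:3) {
    vs <- voxel_size[a]
    c_vox <- center_um[a] / vs - 0.5
    lo <- max(0L, floor(c_vox - 4 * sig_um[a] / vs))
    hi <- min(dims[a] - 1L, ceiling(c_vox + 4 * sig_um[a] / vs))
    if (lo > hi) return(vol)  # entirely outside; caller validates placement
    idx[[a]] <- lo:hi
    w[[a]] <- dnorm((idx[[a]] + 0.5) * vs, center_um[a], sig_um[a]) * vs
  }
  contrib <- amplitude * (w[[1]] %o% w[[2]] %o% w[[3]])
  vol[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L] <-
    vol[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L] + contrib
  vol
}

#' Render a single noiseless 3D spot volume
#'
#' Utility for building detection fixtures: a constant-background volume with
#' one integrated-amplitude Gaussian spot. The sum of the spot contribution
#' over the volume approximates \code{amplitude} (truncated at 4 sigma).
#'
#' @param dims volume dimensions c(nz, ny, nx).
#' @param voxel_size voxel size c(z, y, x) in um.
#' @param center_um spot centre c(z, y, x) in um (voxel i spans centre
#'   (i + 0.5) * voxel_size, 0-based).
#' @param amplitude integrated spot intensity (photons).
#' @param sigma_xy,sigma_z PSF sigmas (um).
#' @param background constant background level.
#' @return a (nz, ny, nx) array.
#' @export
renderSpotVolume <- function(dims, voxel_size, center_um, amplitude,
                             sigma_xy = 0.13, sigma_z = 0.6, background = 0) {
  vol <- array(background, dims)
  addSpot(vol, center_um, amplitude, voxel_size, sigma_xy, sigma_z)
}

# deterministic-ish cell placement: jittered grid, guaranteed separation
placeCells <- function(n, acq, margin_um = 1.3, jitter_um = 0.25) {
  W_x <- acq@n_x * acq@pixel_size
  W_y <- acq@n_y * acq@pixel_size
  mx <- min(margin_um, W_x / 4)
  my <- min(margin_um, W_y / 4)
  k <- ceiling(sqrt(n))
  sx <- (W_x - 2 * mx) / k
  sy <- (W_y - 2 * my) / k
  if (n > 1 && min(sx, sy) < 2 * jitter_um + 0.5)
    stop("field too small to place ", n, " cells without overlap")
  gx <- mx + (rep(seq_len(k), k) - 0.5) * sx
  gy <- my + (rep(seq_len(k), each = k) - 0.5) * sy
  pick <- sample.int(k * k, n)
  z_extent <- acq@n_z * acq@z_step
  data.frame(
    z = z_extent * runif(n, 0.42, 0.58),
    y = gy[pick] + runif(n, -jitter_um, jitter_um),
    x = gx[pick] + runif(n, -jitter_um, jitter_um))
}

#' Render a full synthetic two-channel 3D movie
#'
#' Places one cell per ground-truth row in the field; each cell carries a
#' green focus (proximal array) and a red focus (distal array) ~0.4-0.5 um
#' apart whose integrated intensities double at the cell's true replication
#' times with finite rise time and common photobleaching. Foci drift with the
#' cell (Gaussian random walk). Photon shot noise is Poisson; read noise is
#' additive Gaussian; negative counts are clamped to zero.
#'
#' @param truth ground-truth table from [sampleCellKinetics()].
#' @param layout the [LocusLayout-class] (sets the green-red offset via the
#'   genomic distance, ~0.015 um/kb of chromatin).
#' @param acq an [AcquisitionConfig-class].
#' @param seed RNG seed (NULL = caller's RNG state).
#' @param drift_sd per-frame lateral drift step sd (um).
#' @return a [MovieStack-class] whose \code{truth} slot is the input table
#'   and whose \code{spots} slot gives each focus' initial position.
#' @examples
#' acq <- acquisitionConfig(n_frames = 10, n_y = 48, n_x = 48)
#' gt <- sampleCellKinetics(nominalLocusLayout(),
#'                          scenarioConfig(n_cells = 2, seed = 1))
#' mv <- renderMovie(gt, nominalLocusLayout(), acq, seed = 1)
#' @export
renderMovie <- function(truth, layout, acq, seed = NULL, drift_sd = 0.02) {
  stopifnot(is(acq, "AcquisitionConfig"), is(layout, "LocusLayout"))
  validObject(acq)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  nt <- as.integer(acq@n_frames)
  nz <- as.integer(acq@n_z); ny <- as.integer(acq@n_y); nx <- as.integer(acq@n_x)
  vs <- c(acq@z_step, acq@pixel_size, acq@pixel_size)
  times <- (seq_len(nt) - 1) * acq@frame_interval
  tau <- acq@rise_time / 4

  arr <- array(0, c(nt, 2L, nz, ny, nx))
  spots <- data.frame(cell_id = character(), channel = character(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      t_rep = numeric())
  pos0 <- NULL
  drift <- NULL
  if (n > 0) {
    anchors <- placeCells(n, acq)
    offset_um <- 0.015 * attr(locusGeometry(layout), "exact")$mid_to_mid_kb
    theta <- runif(n, 0, 2 * pi)
    # pos0[[ch]] is an n x 3 matrix of (z, y, x) positions in um
    pos0 <- list(as.matrix(anchors)[, , drop = FALSE],
                 cbind(anchors$z + runif(n, -0.15, 0.15),
                       anchors$y + offset_um * sin(theta),
                       anchors$x + offset_um * cos(theta)))
    lims <- c(nz, ny, nx) * vs
    for (ch in 1:2) {
      p <- pos0[[ch]]
      if (any(p < 0.4) || any(sweep(p, 2, lims - 0.4) > 0))
        stop("spots placed outside the field; enlarge the field or reduce n")
    }
    drift <- lapply(seq_len(n), function(i) {
      steps <- cbind(rnorm(nt - 1, sd = drift_sd / 3),  # z drifts less
                     rnorm(nt - 1, sd = drift_sd),
                     rnorm(nt - 1, sd = drift_sd))
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    })
    t_rep <- cbind(truth$t_rep_array1, truth$t_rep_array2)
    spots <- data.frame(
      cell_id = rep(truth$cell_id, 2),
      channel = rep(c("green", "red"), each = n),
      z_um = c(pos0[[1]][, 1], pos0[[2]][, 1]),
      y_um = c(pos0[[1]][, 2], pos0[[2]][, 2]),
      x_um = c(pos0[[1]][, 3], pos0[[2]][, 3]),
      t_rep = c(t_rep[, 1], t_rep[, 2]))
    amp <- array(0, c(nt, 2L, n))
    for (ch in 1:2) for (i in seq_len(n))
      amp[, ch, i] <- sigmoidTraceModel(times, acq@spot_amplitude,
                                        acq@spot_amplitude, t_rep[i, ch],
                                        tau, acq@bleach_rate)
  }

  for (t in seq_len(nt)) {
    for (ch in 1:2) {
      vol <- array(acq@background_level, c(nz, ny, nx))
      if (n > 0) {
        for (i in seq_len(n)) {
          vol <- addSpot(vol, pos0[[ch]][i, ] + drift[[i]][t, ],
                         amp[t, ch, i], vs, acq@psf_sigma_xy, acq@psf_sigma_z)
        }
      }
      noisy <- rpois(length(vol), vol) +
        rnorm(length(vol), sd = acq@read_noise_sd)
      arr[t, ch, , , ] <- pmax(noisy, 0)
    }
  }
  new("MovieStack", data = arr, metadata = acq,
      truth = if (n > 0) truth else data.frame(), spots = spots)
}

#' Simulate a complete replication movie for one scenario
#'
#' [sampleCellKinetics()] followed by [renderMovie()].
#'
#' @inheritParams renderMovie
#' @param scenario a [ScenarioConfig-class].
#' @return a [MovieStack-class].
#' @export
simulateReplicationMovie <- function(layout, scenario,
                                     acq = acquisitionConfig(), seed = NULL,
                                     drift_sd = 0.02) {
  truth <- sampleCellKinetics(layout, scenario)
  renderMovie(truth, layout, acq, seed = seed, drift_sd = drift_sd)
}
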