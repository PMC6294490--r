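#' Construct acquisition parameters
#'
#' Defaults emulate a spinning-disk confocal time lapse of a tagged yeast
#' locus: 180 one-minute frames, 12 z-sections 0.7 um apart, a 128x128 field
#' at 0.107 um/pixel, a near-diffraction-limited PSF, mono-exponential
#' photobleaching, and a focus whose integrated intensity doubles from
#' \code{spot_amplitude} over a finite \code{rise_time} (the time the fork
#' needs to duplicate the array: 10 kb at 1.5 kb/min, ~6.7 min).
#'
#' @param n_frames,frame_interval frames and interval (min).
#' @param n_z,z_step z-sections and spacing (um).
#' @param n_y,n_x field size (pixels).
#' @param pixel_size lateral pixel size (um).
#' @param psf_sigma_xy,psf_sigma_z PSF Gaussian sigmas (um).
#' @param background_level mean background (photons/voxel).
#' @param read_noise_sd Gaussian read noise sd (photons).
#' @param bleach_rate photobleaching rate (1/min).
#' @param spot_amplitude pre-replication integrated focus intensity (photons).
#' @param rise_time duration of the intensity doubling (min).
#' @return an [AcquisitionConfig-class].
#' @export
acquisitionConfig <- function(n_frames = 180, frame_interval = 1,
                              n_z = 12, z_step = 0.7,
                              n_y = 128, n_x = 128, pixel_size = 0.107,
                              psf_sigma_xy = 0.13, psf_sigma_z = 0.6,
                              background_level = 100, read_noise_sd = 5,
                              bleach_rate = 0.002, spot_amplitude = 3000,
                              rise_time = 10 / 1.5) {
  new("AcquisitionConfig", n_frames = n_frames,
      frame_interval = frame_interval, n_z = n_z, z_step = z_step,
      n_y = n_y, n_x = n_x, pixel_size = pixel_size,
      psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
      background_level = background_level, read_noise_sd = read_noise_sd,
      bleach_rate = bleach_rate, spot_amplitude = spot_amplitude,
      rise_time = rise_time)
}

#' Bleached logistic step model for a focus intensity trace
#'
#' I(t) = exp(-bleach_rate t) * (B + A / (1 + exp(-(t - t_mid)/tau))).
#' With A = B the plateau doubles the baseline, as expected when an operator
#' array is duplicated and recruits twice the repressor-fluorophore.
#'
#' @param t times (min).
#' @param B baseline intensity.
#' @param A step amplitude.
#' @param t_mid mid-rise time (min).
#' @param tau logistic rise scale (min).
#' @param bleach_rate photobleaching rate (1/min).
#' @return model intensities at \code{t}.
#' @export
sigmoidTraceModel <- function(t, B, A, t_mid, tau, bleach_rate = 0) {
  exp(-bleach_rate * t) * (B + A / (1 + exp(-(t - t_mid) / tau)))
}

#' Render a noisy two-channel intensity trace for one cell
#'
#' Each channel follows [sigmoidTraceModel()] with amplitude equal to its
#' baseline (intensity doubling), mid-rise at the cell's true replication
#' time of the corresponding array, rise scale \code{rise_time/4}, common
#' photobleaching, and additive Gaussian noise.
#'
#' @param gt one row of the [sampleCellKinetics()] table (or any list with
#'   \code{t_rep_array1}, \code{t_rep_array2} and optionally \code{cell_id}).
#' @param acq an [AcquisitionConfig-class].
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param baseline per-channel baselines c(green, red); defaults to
#'   \code{spot_amplitude} for both.
#' @return a [CellTrace-class] with provenance \code{"simulated"}.
#' @examples
#' acq <- acquisitionConfig(bleach_rate = 0)
#' tr <- renderTrace(list(cell_id = "c1", t_rep_array1 = 60, t_rep_array2 = 80),
#'                   acq)
#' @export
renderTrace <- function(gt, acq, noise_sd = 0, baseline = NULL) {
  stopifnot(is(acq, "AcquisitionConfig"))
  validObject(acq)
  times <- (seq_len(acq@n_frames) - 1) * acq@frame_interval
  tau <- acq@rise_time / 4
  if (is.null(baseline)) baseline <- rep(acq@spot_amplitude, 2)
  g <- sigmoidTraceModel(times, baseline[1], baseline[1], gt$t_rep_array1,
                         tau, acq@bleach_rate)
  r <- sigmoidTraceModel(times, baseline[2], baseline[2], gt$t_rep_array2,
                         tau, acq@bleach_rate)
  if (noise_sd > 0) {
    g <- g + rnorm(length(times), sd = noise_sd)
    r <- r + rnorm(length(times), sd = noise_sd)
  }
  new("CellTrace",
      cell_id = if (!is.null(gt$cell_id)) as.character(gt$cell_id) else "cell",
      times = times, intensity_green = g, intensity_red = r,
      provenance = "simulated")
}

#' Simulate a cohort of ground-truthed intensity traces
#'
#' Convenience wrapper: [sampleCellKinetics()] then [renderTrace()] per cell.
#'
#' @param layout a [LocusLayout-class].
#' @param scenario a [ScenarioConfig-class].
#' @param acq an [AcquisitionConfig-class].
#' @param noise_frac Gaussian noise sd as a fraction of the baseline.
#' @return list with \code{truth} (ground-truth table) and \code{traces}
#'   (list of [CellTrace-class]).
#' @export
simulateCohortTraces <- function(layout, scenario, acq = acquisitionConfig(),
                                 noise_frac = 0.02) {
  truth <- sampleCellKinetics(layout, scenario)
  traces <- lapply(seq_len(nrow(truth)), function(i)
    renderTrace(truth[i, ], acq, noise_sd = noise_frac * acq@spot_amplitude))
  list(truth = truth, traces = traces)
}
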