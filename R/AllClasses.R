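# Central S4 containers.
#
# Conventions used throughout the package:
#  - genomic coordinates are 1-based bp, as printed in strain tables;
#  - voxel indices are 0-based in (z, y, x) order, the centre of voxel i lying
#    at (i + 0.5) * voxel_size on that axis;
#  - times are minutes, distances kb (genomic) or micrometres (image space);
#  - intensities are photons (or arbitrary units for traces read from file).

#' LocusLayout: geometry of the tagged chromosomal region
#'
#' Describes the engineered locus: a replication origin, two operator-array
#' insertion points flanking the interval of interest (array 1 = lacO/green,
#' array 2 = tetO/red, arrays extending away from the interval), and an
#' optional replication obstacle (a G-quadruplex motif) between them.
#'
#' @slot origin_pos replication origin position (bp), upstream of array 1.
#' @slot array1_pos,array2_pos insertion coordinates (bp) of the two operator
#'   arrays; their difference is the inner (edge-to-edge) spacing.
#' @slot array_len length of each operator array (kb).
#' @slot obstacle_pos obstacle insertion coordinate (bp), or \code{NA}.
#' @slot obstacle_strand \code{"lagging"}, \code{"leading"} or \code{NA}.
#' @seealso [locusLayout()], [nominalLocusLayout()], [chrIVLocusLayout()],
#'   [locusGeometry()]
#' @exportClass LocusLayout
setClass("LocusLayout",
  slots = c(origin_pos = "numeric", array1_pos = "numeric",
            array2_pos = "numeric", array_len = "numeric",
            obstacle_pos = "numeric", obstacle_strand = "character"),
  prototype = list(obstacle_pos = NA_real_, obstacle_strand = NA_character_))

setValidity("LocusLayout", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1 && is.numeric(x)
  if (!one(object@origin_pos) || !one(object@array1_pos) ||
      !one(object@array2_pos) || !one(object@array_len))
    return("positions and array_len must be numeric scalars")
  if (!is.finite(object@array_len) || object@array_len < 0)
    msg <- c(msg, "array_len must be >= 0 kb")
  if (!(object@array1_pos < object@array2_pos))
    msg <- c(msg, "array1_pos must be < array2_pos")
  if (object@origin_pos >= object@array1_pos)
    msg <- c(msg, "origin_pos must lie upstream of array1_pos")
  if (!is.na(object@obstacle_pos)) {
    if (!(object@obstacle_pos > object@array1_pos &&
          object@obstacle_pos < object@array2_pos))
      msg <- c(msg, "obstacle_pos must lie strictly between the arrays")
    if (!is.na(object@obstacle_strand) &&
        !object@obstacle_strand %in% c("lagging", "leading"))
      msg <- c(msg, "obstacle_strand must be 'lagging' or 'leading'")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: per-strain simulation scenario
#'
#' Parameters of the per-cell replication-kinetics generator for one strain or
#' condition. Fork speeds vary from cell to cell (log-normal with the given
#' mean and coefficient of variation); if the layout carries an obstacle, a
#' fraction of cells (\code{folded_fraction}, the cells in which the structure
#' is folded) incur an additional pause before the distal array.
#'
#' @slot label strain/scenario name.
#' @slot fork_speed_mean mean fork speed (kb/min).
#' @slot fork_speed_cv cell-to-cell coefficient of variation of fork speed.
#' @slot pause_mean expected pause at the obstacle (min) for paused cells.
#' @slot folded_fraction probability in [0, 1] that the obstacle is folded in
#'   a given cell.
#' @slot n_cells number of cells to simulate.
#' @slot seed RNG seed (\code{NA} = do not reseed).
#' @slot firing_time_mean,firing_time_sd origin firing time offset (min).
#' @slot pause_model \code{"exponential"} (memoryless barrier) or
#'   \code{"fixed"} (deterministic pause, for exact tests).
#' @seealso [scenarioConfig()], [sampleCellKinetics()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  slots = c(label = "character", fork_speed_mean = "numeric",
            fork_speed_cv = "numeric", pause_mean = "numeric",
            folded_fraction = "numeric", n_cells = "numeric",
            seed = "numeric", firing_time_mean = "numeric",
            firing_time_sd = "numeric", pause_model = "character"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (!is.finite(object@fork_speed_mean) || object@fork_speed_mean <= 0)
    msg <- c(msg, "fork_speed_mean must be > 0")
  if (object@fork_speed_cv < 0) msg <- c(msg, "fork_speed_cv must be >= 0")
  if (object@pause_mean < 0) msg <- c(msg, "pause_mean must be >= 0")
  if (object@folded_fraction < 0 || object@folded_fraction > 1)
    msg <- c(msg, "folded_fraction must be in [0, 1]")
  if (!is.finite(object@n_cells) || object@n_cells < 0 ||
      object@n_cells != round(object@n_cells))
    msg <- c(msg, "n_cells must be a non-negative integer")
  if (object@firing_time_sd < 0) msg <- c(msg, "firing_time_sd must be >= 0")
  if (!object@pause_model %in% c("exponential", "fixed"))
    msg <- c(msg, "pause_model must be 'exponential' or 'fixed'")
  if (length(msg)) msg else TRUE
})

#' AcquisitionConfig: imaging/acquisition parameters
#'
#' Defaults follow a spinning-disk confocal time lapse: 1-min frame intervals
#' and 12 z-sections 0.7 um apart.
#'
#' @slot n_frames number of time points.
#' @slot frame_interval min between frames.
#' @slot n_z,z_step z-sections and spacing (um).
#' @slot n_y,n_x field size in pixels.
#' @slot pixel_size lateral pixel size (um).
#' @slot psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas (um).
#' @slot background_level mean background (photons/voxel).
#' @slot read_noise_sd Gaussian read noise sd (photons).
#' @slot bleach_rate mono-exponential photobleaching rate (1/min).
#' @slot spot_amplitude pre-replication integrated focus intensity (photons).
#' @slot rise_time duration of the intensity doubling (min); by default the
#'   time a 1.5 kb/min fork needs to duplicate a 10 kb array.
#' @seealso [acquisitionConfig()], [renderTrace()], [renderMovie()]
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  slots = c(n_frames = "numeric", frame_interval = "numeric",
            n_z = "numeric", z_step = "numeric",
            n_y = "numeric", n_x = "numeric", pixel_size = "numeric",
            psf_sigma_xy = "numeric", psf_sigma_z = "numeric",
            background_level = "numeric", read_noise_sd = "numeric",
            bleach_rate = "numeric", spot_amplitude = "numeric",
            rise_time = "numeric"))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  pos <- c(n_frames = object@n_frames, frame_interval = object@frame_interval,
           n_z = object@n_z, z_step = object@z_step, n_y = object@n_y,
           n_x = object@n_x, pixel_size = object@pixel_size,
           psf_sigma_xy = object@psf_sigma_xy, psf_sigma_z = object@psf_sigma_z,
           spot_amplitude = object@spot_amplitude, rise_time = object@rise_time)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste0(paste(bad, collapse = ", "), " must be > 0"))
  if (object@background_level < 0) msg <- c(msg, "background_level must be >= 0")
  if (object@read_noise_sd < 0) msg <- c(msg, "read_noise_sd must be >= 0")
  if (object@bleach_rate < 0) msg <- c(msg, "bleach_rate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MovieStack: a multi-dimensional fluorescence movie
#'
#' Intensity data with axes (t, channel, z, y, x) plus acquisition metadata.
#' Simulated movies additionally carry the generator's ground truth: the
#' per-cell kinetics table and the initial spot positions.
#'
#' @slot data 5-d numeric array, axes (t, channel, z, y, x); channel 1 is
#'   green (proximal array), channel 2 red (distal array).
#' @slot metadata an [AcquisitionConfig-class].
#' @slot truth per-cell ground-truth kinetics (empty for measured movies).
#' @slot spots ground-truth spot table (cell, channel, initial position).
#' @exportClass MovieStack
setClass("MovieStack",
  slots = c(data = "array", metadata = "AcquisitionConfig",
            truth = "data.frame", spots = "data.frame"))

setValidity("MovieStack", function(object) {
  d <- dim(object@data)
  m <- object@metadata
  if (length(d) != 5)
    return("data must have 5 axes (t, channel, z, y, x)")
  want <- c(m@n_frames, 2, m@n_z, m@n_y, m@n_x)
  if (!all(d == want))
    return(sprintf("data dim (%s) does not match metadata (%s)",
                   paste(d, collapse = "x"), paste(want, collapse = "x")))
  if (any(object@data < 0)) return("intensities must be >= 0")
  TRUE
})

#' CellTrace: per-cell two-channel focus intensity time series
#'
#' @slot cell_id cell identifier.
#' @slot times acquisition times (min), strictly increasing.
#' @slot intensity_green,intensity_red background-subtracted integrated focus
#'   intensities aligned to \code{times}; \code{NA} marks frames where the
#'   focus was not detected (gaps are never interpolated).
#' @slot provenance \code{"simulated"} or \code{"measured"}.
#' @exportClass CellTrace
setClass("CellTrace",
  slots = c(cell_id = "character", times = "numeric",
            intensity_green = "numeric", intensity_red = "numeric",
            provenance = "character"))

setValidity("CellTrace", function(object) {
  n <- length(object@times)
  if (length(object@intensity_green) != n || length(object@intensity_red) != n)
    return("times and intensity vectors must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!object@provenance %in% c("simulated", "measured"))
    return("provenance must be 'simulated' or 'measured'")
  TRUE
})

#' FocusTrack: one focus followed through time in one channel
#'
#' @slot channel \code{"green"} or \code{"red"}.
#' @slot detections time-ordered detection table (frame, voxel and um
#'   positions, response, intensity); at most one row per frame.
#' @slot gaps frames inside the track span with no detection (gap-closed).
#' @exportClass FocusTrack
setClass("FocusTrack",
  slots = c(channel = "character", detections = "data.frame", gaps = "numeric"))

setValidity("FocusTrack", function(object) {
  d <- object@detections
  if (!all(c("frame", "z_um", "y_um", "x_um") %in% names(d)))
    return("detections must have frame, z_um, y_um, x_um columns")
  if (anyDuplicated(d$frame)) return("at most one detection per frame")
  if (is.unsorted(d$frame)) return("detections must be time-ordered")
  TRUE
})

#' SigmoidFit: bleach-aware logistic fit of one focus intensity trace
#'
#' Model: I(t) = exp(-bleach_rate * t) * (B + A / (1 + exp(-(t - t_mid)/tau))).
#' \code{t_mid} is the mid-rise point used for replication timing; the plateau
#' fold-increase (B + A)/B is 2 for a clean array duplication.
#'
#' @slot channel channel label.
#' @slot B,A baseline and step amplitude (intensity units).
#' @slot t_mid mid-rise time (min).
#' @slot tau logistic rise scale (min).
#' @slot bleach_rate fitted bleaching rate (1/min).
#' @slot r_squared goodness of fit.
#' @slot converged whether the optimizer converged.
#' @slot t_range first and last fitted time (min), used by QC edge margins.
#' @seealso [fitIntensitySigmoid()], [tMid()], [plateauFold()]
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  slots = c(channel = "character", B = "numeric", A = "numeric",
            t_mid = "numeric", tau = "numeric", bleach_rate = "numeric",
            r_squared = "numeric", converged = "logical",
            t_range = "numeric"))

setValidity("SigmoidFit", function(object) {
  if (isTRUE(object@converged)) {
    if (!is.finite(object@tau) || object@tau <= 0)
      return("tau must be > 0 for a converged fit")
  }
  if (is.finite(object@r_squared) && object@r_squared > 1 + 1e-9)
    return("r_squared must be <= 1")
  TRUE
})

#' CohortResult: summary of one strain's replication-event cohort
#'
#' @slot label strain/scenario name.
#' @slot n number of QC-passed cells.
#' @slot mean_delta_t mean replication delay (min).
#' @slot sem standard error of the mean (sample sd / sqrt(n), min).
#' @slot mean_rate mean per-cell replication rate (kb/min).
#' @slot breaks,counts fixed-width histogram of delta t anchored at 0.
#' @seealso [summarizeCohort()]
#' @exportClass CohortResult
setClass("CohortResult",
  slots = c(label = "character", n = "numeric", mean_delta_t = "numeric",
            sem = "numeric", mean_rate = "numeric",
            breaks = "numeric", counts = "numeric"))

setValidity("CohortResult", function(object) {
  if (object@n < 2) return("a cohort needs at least 2 events")
  if (length(object@breaks) != length(object@counts) + 1)
    return("breaks must be one longer than counts")
  if (sum(object@counts) != object@n)
    return("histogram counts must sum to n")
  TRUE
})

#' ResamplingTestResult: two-sample Monte Carlo resampling test
#'
#' Permutation (or pooled-bootstrap) test of the difference in cohort means,
#' with the add-one correction p = (k + 1)/(B + 1), so p is never exactly 0.
#'
#' @slot observed_diff observed difference of means (min).
#' @slot n_iterations resampling iterations.
#' @slot p_value achieved significance level, in (0, 1].
#' @slot n_exceed resampled statistics >= the observed one.
#' @slot two_sided whether the absolute difference was used.
#' @slot seed RNG seed used (NA if the caller's RNG state was used).
#' @slot method \code{"permutation"} or \code{"bootstrap"}.
#' @seealso [resamplingTest()], [pValue()]
#' @exportClass ResamplingTestResult
setClass("ResamplingTestResult",
  slots = c(observed_diff = "numeric", n_iterations = "numeric",
            p_value = "numeric", n_exceed = "numeric", two_sided = "logical",
            seed = "numeric", method = "character"))

setValidity("ResamplingTestResult", function(object) {
  if (object@p_value <= 0 || object@p_value > 1)
    return("p_value must be in (0, 1]")
  expect <- (object@n_exceed + 1) / (object@n_iterations + 1)
  if (abs(object@p_value - expect) > 1e-12)
    return("p_value must equal (n_exceed + 1)/(n_iterations + 1)")
  TRUE
})

#' MeltingCurve: normalized UV melting curve of a folded oligonucleotide
#'
#' @slot temps temperatures (deg C), strictly increasing.
#' @slot signal normalized A295 signal (approx. folded fraction).
#' @slot label oligo name.
#' @exportClass MeltingCurve
setClass("MeltingCurve",
  slots = c(temps = "numeric", signal = "numeric", label = "character"))

setValidity("MeltingCurve", function(object) {
  if (length(object@temps) != length(object@signal))
    return("temps and signal must have equal length")
  if (length(object@temps) > 1 && any(diff(object@temps) <= 0))
    return("temps must be strictly increasing")
  if (any(!is.finite(object@signal))) return("signal must be finite")
  TRUE
})

#' MeltingFit: two-state van 't Hoff fit of a melting curve
#'
#' theta(T) = 1 / (1 + exp(-(dH/R) (1/T_K - 1/Tm_K))) in absolute temperature,
#' with the entropy fixed by the midpoint condition dS = dH/Tm_K (unimolecular
#' two-state equilibrium). theta(Tm) = 0.5 by construction.
#'
#' @slot Tm melting temperature (deg C).
#' @slot dH_vH van 't Hoff unfolding enthalpy (kcal/mol).
#' @slot dS_vH unfolding entropy at the midpoint, dH/Tm_K (kcal/mol/K).
#' @slot baseline residual linear baselines c(u0, u1, f0, f1) for the unfolded
#'   and folded states (identity c(0, 0, 1, 0) when not fitted).
#' @slot r_squared goodness of fit.
#' @slot converged whether the fit converged.
#' @slot flags diagnostics, e.g. \code{"transition_not_bracketed"} or
#'   \code{"non_standard_increasing"} (a refolding-type curve, dH < 0).
#' @seealso [fitTwoStateMelting()], [foldedFraction()]
#' @exportClass MeltingFit
setClass("MeltingFit",
  slots = c(Tm = "numeric", dH_vH = "numeric", dS_vH = "numeric",
            baseline = "numeric", r_squared = "numeric",
            converged = "logical", flags = "character"))

#' GelLaneProfile: 1D densitometric profile of one gel lane
#'
#' @slot positions migration positions (pixel or mm), increasing.
#' @slot intensity lane intensity (arbitrary units).
#' @slot band_windows named list of c(lo, hi) intervals; canonical names are
#'   \code{primer}, \code{stall} and \code{full_length}.
#' @slot time reaction time point (min) for time courses, else \code{NA}.
#' @exportClass GelLaneProfile
setClass("GelLaneProfile",
  slots = c(positions = "numeric", intensity = "numeric",
            band_windows = "list", time = "numeric"),
  prototype = list(time = NA_real_))

setValidity("GelLaneProfile", function(object) {
  if (length(object@positions) != length(object@intensity))
    return("positions and intensity must have equal length")
  if (is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  if (length(object@band_windows)) {
    ok <- vapply(object@band_windows,
                 function(w) is.numeric(w) && length(w) == 2 && w[1] < w[2],
                 logical(1))
    if (!all(ok)) return("band_windows must be c(lo, hi) with lo < hi")
    if (is.null(names(object@band_windows)))
      return("band_windows must be named")
  }
  TRUE
})
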