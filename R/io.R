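# File interfaces: multi-page TIFF movies (with a YAML sidecar carrying the
# acquisition metadata and intensity scale), YAML configs, tidy CSV traces.

#' Write / read a movie as multi-page TIFF
#'
#' Pages are ordered t-major, then channel, then z (t, channel, z); each page
#' is a (y, x) float image. Intensities are scaled into [0, 1] by the global
#' maximum; the scale and the acquisition metadata go to a YAML sidecar
#' (\code{<path>.yaml}) so the round trip is lossless up to float precision.
#'
#' @param movie a [MovieStack-class].
#' @param path output TIFF path.
#' @return \code{writeMovieTIFF}: invisibly, the path;
#'   \code{readMovieTIFF}: a [MovieStack-class] (without ground truth).
#' @export
writeMovieTIFF <- function(movie, path) {
  stopifnot(is(movie, "MovieStack"))
  d <- dim(movie@data)
  scale <- max(movie@data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    k <- k + 1
    pages[[k]] <- matrix(movie@data[t, ch, z, , ] / scale, d[4], d[5])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  m <- movie@metadata
  meta <- list(axes = "TCZYX", scale = scale,
               acquisition = list(
                 n_frames = m@n_frames, frame_interval = m@frame_interval,
                 n_z = m@n_z, z_step = m@z_step, n_y = m@n_y, n_x = m@n_x,
                 pixel_size = m@pixel_size, psf_sigma_xy = m@psf_sigma_xy,
                 psf_sigma_z = m@psf_sigma_z,
                 background_level = m@background_level,
                 read_noise_sd = m@read_noise_sd, bleach_rate = m@bleach_rate,
                 spot_amplitude = m@spot_amplitude, rise_time = m@rise_time))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  acq <- do.call(acquisitionConfig, meta$acquisition)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(acq@n_frames, 2, acq@n_z, acq@n_y, acq@n_x)
  arr <- array(0, d)
  k <- 0
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    k <- k + 1
    arr[t, ch, z, , ] <- pages[[k]] * meta$scale
  }
  new("MovieStack", data = arr, metadata = acq,
      truth = data.frame(), spots = data.frame())
}

#' Read a scenario or acquisition config from YAML
#'
#' The YAML keys are the arguments of [scenarioConfig()] /
#' [acquisitionConfig()].
#'
#' @param path YAML file path.
#' @return a [ScenarioConfig-class] / [AcquisitionConfig-class].
#' @export
scenarioFromYAML <- function(path) {
  do.call(scenarioConfig, yaml::read_yaml(path))
}

#' @rdname scenarioFromYAML
#' @export
acquisitionFromYAML <- function(path) {
  do.call(acquisitionConfig, yaml::read_yaml(path))
}

#' Tidy-table conversions for traces
#'
#' @param traces list of [CellTrace-class].
#' @return long data.frame with \code{cell_id}, \code{channel}, \code{t_min},
#'   \code{intensity}.
#' @export
tracesToTable <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr@cell_id,
               channel = rep(c("green", "red"), each = length(tr@times)),
               t_min = rep(tr@times, 2),
               intensity = c(tr@intensity_green, tr@intensity_red))
  }))
}

#' @rdname tracesToTable
#' @param table a long trace table as produced by [tracesToTable()] (e.g.
#'   read from CSV).
#' @param provenance provenance label for the rebuilt traces.
#' @export
tracesFromTable <- function(table, provenance = "measured") {
  stopifnot(all(c("cell_id", "channel", "t_min", "intensity") %in%
                names(table)))
  lapply(split(table, table$cell_id), function(d) {
    g <- d[d$channel == "green", ]
    r <- d[d$channel == "red", ]
    g <- g[order(g$t_min), ]; r <- r[order(r$t_min), ]
    stopifnot(all(g$t_min == r$t_min))
    new("CellTrace", cell_id = as.character(d$cell_id[1]), times = g$t_min,
        intensity_green = g$intensity, intensity_red = r$intensity,
        provenance = provenance)
  })
}
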