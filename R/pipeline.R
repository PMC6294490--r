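# End-to-end movie pipeline: detect -> measure -> link -> pair -> fit -> QC.

#' Analyze a movie into per-cell traces
#'
#' Runs [detectSpotsMovie()], [linkTracks()] per channel and
#' [assembleCellTraces()].
#'
#' @param movie a [MovieStack-class].
#' @param max_displacement,max_gap tracking parameters, see [linkTracks()].
#' @param pairing_radius,min_length pairing parameters, see
#'   [assembleCellTraces()].
#' @param ... passed to [detectSpotsMovie()] (detection and measurement
#'   parameters).
#' @return list with \code{traces}, \code{positions}, \code{unpaired},
#'   \code{tracks_green}, \code{tracks_red} and the raw \code{detections}.
#' @export
analyzeMovie <- function(movie, max_displacement = 0.8, max_gap = 2,
                         pairing_radius = 1.0, min_length = 10, ...) {
  stopifnot(is(movie, "MovieStack"))
  m <- movie@metadata
  det <- detectSpotsMovie(movie, ...)
  tg <- linkTracks(det[det$channel == "green", , drop = FALSE], "green",
                   max_displacement, max_gap)
  tr <- linkTracks(det[det$channel == "red", , drop = FALSE], "red",
                   max_displacement, max_gap)
  times <- (seq_len(m@n_frames) - 1) * m@frame_interval
  asm <- assembleCellTraces(tg, tr, times, pairing_radius, min_length)
  c(asm, list(tracks_green = tg, tracks_red = tr, detections = det))
}

#' Movie to QC-filtered replication events
#'
#' The full chain: analyze the movie, fit both channels of every trace,
#' compute delta_t and apply [qcFilter()].
#'
#' @param movie a [MovieStack-class].
#' @param distance_kb inter-array distance for rates (kb).
#' @param qc named list of [qcFilter()] arguments (optional overrides).
#' @param ... passed to [analyzeMovie()].
#' @return list with \code{events} (QC-passed), \code{failed},
#'   \code{all_events}, \code{fits}, \code{analysis}.
#' @export
movieToEvents <- function(movie, distance_kb = 30, qc = list(), ...) {
  analysis <- analyzeMovie(movie, ...)
  fitres <- fitCohortTraces(analysis$traces, distance_kb = distance_kb)
  flt <- do.call(qcFilter, c(list(events = fitres$events), qc))
  list(events = flt$passed, failed = flt$failed,
       all_events = fitres$events, fits = fitres$fits, analysis = analysis)
}

#' Plot a cell trace with its fitted steps
#'
#' Base-graphics diagnostic plot: both channels with the fitted bleached
#' logistic curves and dashed vertical lines at the mid-rise points.
#'
#' @param trace a [CellTrace-class].
#' @param fits optional list with \code{green} and \code{red}
#'   [SigmoidFit-class] objects (e.g. one element of
#'   [fitCohortTraces()]'s \code{fits}).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the trace.
#' @export
plotTrace <- function(trace, fits = NULL, ...) {
  stopifnot(is(trace, "CellTrace"))
  t <- trace@times
  ylim <- range(c(trace@intensity_green, trace@intensity_red), na.rm = TRUE)
  graphics::plot(t, trace@intensity_green, col = "darkgreen", pch = 16,
                 cex = 0.5, xlab = "time (min)", ylab = "focus intensity",
                 ylim = ylim, main = trace@cell_id, ...)
  graphics::points(t, trace@intensity_red, col = "firebrick", pch = 16,
                   cex = 0.5)
  if (!is.null(fits)) {
    tt <- seq(min(t), max(t), length.out = 400)
    for (ch in c("green", "red")) {
      f <- fits[[ch]]
      if (is.null(f) || !f@converged) next
      col <- if (ch == "green") "darkgreen" else "firebrick"
      graphics::lines(tt, sigmoidTraceModel(tt, f@B, f@A, f@t_mid, f@tau,
                                            f@bleach_rate), col = col)
      graphics::abline(v = f@t_mid, lty = 2, col = col)
    }
  }
  invisible(trace)
}
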