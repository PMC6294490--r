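# Replication events: delta t between the two channel mid-points, rates over
# the inter-array distance, and machine-readable QC.
#
# A "replication event" is one row of the events table:
#   cell_id, t_mid_green, t_mid_red, delta_t (min), distance_kb,
#   rate (kb/min, NA unless delta_t > 0), per-channel fit summaries
#   (conv_*, r2_*, fold_*), window_start/window_end, flags, qc_pass,
#   qc_reasons.

#' Compute a replication event from a pair of channel fits
#'
#' delta_t = t_mid(red) - t_mid(green): the time the fork needs to travel
#' from the proximal (lacO/green) to the distal (tetO/red) array, i.e. the
#' replication time of the mid-array to mid-array interval. The rate is
#' distance_kb / delta_t. Negative or zero delta_t (a fork arriving from the
#' distal side, against the assumed orientation) is retained but flagged
#' \code{reverse_orientation} / \code{zero_delta}.
#'
#' @param fit_green,fit_red [SigmoidFit-class] for the two channels.
#' @param cell_id cell identifier.
#' @param distance_kb inter-array mid-to-mid distance; the nominal layout
#'   gives 30 kb (the coordinate-accurate variant 30.6).
#' @return one-row data.frame (see file header for columns).
#' @examples
#' g <- fitIntensitySigmoid(0:179, sigmoidTraceModel(0:179, 100, 100, 60, 2))
#' r <- fitIntensitySigmoid(0:179, sigmoidTraceModel(0:179, 100, 100, 80, 2),
#'                          channel = "red")
#' computeDeltaT(g, r)  # delta_t = 20 min, rate 1.5 kb/min
#' @export
computeDeltaT <- function(fit_green, fit_red, cell_id = "cell",
                          distance_kb = 30) {
  stopifnot(is(fit_green, "SigmoidFit"), is(fit_red, "SigmoidFit"))
  conv <- fit_green@converged && fit_red@converged
  delta <- if (conv) fit_red@t_mid - fit_green@t_mid else NA_real_
  rate <- if (conv && is.finite(delta) && delta > 0) distance_kb / delta
          else NA_real_
  flags <- character()
  if (conv && delta < 0) flags <- c(flags, "reverse_orientation")
  if (conv && delta == 0) flags <- c(flags, "zero_delta")
  win <- c(max(fit_green@t_range[1], fit_red@t_range[1]),
           min(fit_green@t_range[2], fit_red@t_range[2]))
  data.frame(cell_id = as.character(cell_id),
             t_mid_green = fit_green@t_mid, t_mid_red = fit_red@t_mid,
             delta_t = delta, distance_kb = distance_kb, rate = rate,
             conv_green = fit_green@converged, conv_red = fit_red@converged,
             r2_green = fit_green@r_squared, r2_red = fit_red@r_squared,
             fold_green = plateauFold(fit_green),
             fold_red = plateauFold(fit_red),
             window_start = win[1], window_end = win[2],
             flags = paste(flags, collapse = ","),
             qc_pass = if (conv) NA else FALSE,
             qc_reasons = if (conv) "" else "unconverged")
}

#' Fit all traces of a cohort and build the events table
#'
#' @param traces list of [CellTrace-class].
#' @param distance_kb inter-array distance used for rates (kb).
#' @param fix_bleach passed to [fitIntensitySigmoid()].
#' @return list with \code{events} (data.frame, one row per cell) and
#'   \code{fits} (per-cell list of the two [SigmoidFit-class] objects).
#' @export
fitCohortTraces <- function(traces, distance_kb = 30, fix_bleach = FALSE) {
  fits <- lapply(traces, function(tr) {
    list(green = fitIntensitySigmoid(tr@times, tr@intensity_green,
                                     "green", fix_bleach),
         red = fitIntensitySigmoid(tr@times, tr@intensity_red,
                                   "red", fix_bleach))
  })
  names(fits) <- vapply(traces, slot, "", "cell_id")
  events <- do.call(rbind, lapply(seq_along(traces), function(i)
    computeDeltaT(fits[[i]]$green, fits[[i]]$red,
                  traces[[i]]@cell_id, distance_kb)))
  list(events = events, fits = fits)
}

#' Quality-control filter for replication events
#'
#' A cell passes iff both channel fits converged, both r-squared values reach
#' \code{r2_min}, both plateau fold-increases lie inside \code{fold_window}
#' (a clean duplication doubles the intensity), both mid-points sit at least
#' \code{edge_margin_min} minutes inside the observation window (a step at
#' the window edge is not a measured step), and, by default, delta_t > 0
#' (the assay assumes the fork arrives from the origin side). Every failure
#' carries machine-readable reasons.
#'
#' @param events events table from [fitCohortTraces()]/[computeDeltaT()].
#' @param r2_min minimum per-channel goodness of fit.
#' @param fold_window allowed plateau fold-increase range.
#' @param edge_margin_min minimum distance of each mid-point from the window
#'   edges (min).
#' @param require_positive_delta exclude reverse-orientation cells.
#' @return list with \code{passed} and \code{failed} event tables; the
#'   \code{qc_pass}/\code{qc_reasons} columns are filled in both.
#' @export
qcFilter <- function(events, r2_min = 0.8, fold_window = c(1.4, 2.6),
                     edge_margin_min = 5, require_positive_delta = TRUE) {
  if (!nrow(events)) return(list(passed = events, failed = events))
  reasons <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    r <- character()
    if (!(isTRUE(e$conv_green) && isTRUE(e$conv_red))) {
      r <- "unconverged"
    } else {
      if (!isTRUE(e$r2_green >= r2_min) || !isTRUE(e$r2_red >= r2_min))
        r <- c(r, "low_r2")
      folds <- c(e$fold_green, e$fold_red)
      if (any(!is.finite(folds)) || any(folds < fold_window[1]) ||
          any(folds > fold_window[2]))
        r <- c(r, "fold_out_of_range")
      mids <- c(e$t_mid_green, e$t_mid_red)
      if (any(mids < e$window_start + edge_margin_min) ||
          any(mids > e$window_end - edge_margin_min))
        r <- c(r, "edge_margin")
      if (require_positive_delta && !isTRUE(e$delta_t > 0))
        r <- c(r, "nonpositive_delta")
    }
    reasons[[i]] <- r
  }
  pass <- lengths(reasons) == 0
  events$qc_pass <- pass
  events$qc_reasons <- vapply(reasons, paste, "", collapse = ",")
  list(passed = events[pass, , drop = FALSE],
       failed = events[!pass, , drop = FALSE])
}
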