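# Tracking (the linking stage of the foci pipeline): greedy nearest-neighbour
# frame-to-frame assignment with gap closing, then mutual-nearest pairing of
# green and red tracks into per-cell traces.

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment: at each frame, candidate
#' (track, detection) pairs within \code{max_displacement} (physical units,
#' so z anisotropy is already accounted for) are assigned in order of
#' increasing distance, ties broken by higher detection intensity. A track
#' head left unmatched survives up to \code{max_gap} frames (gap closing);
#' leftover detections seed new tracks.
#'
#' @param detections data.frame from [detectSpotsMovie()] (or compatible)
#'   for a single channel: columns \code{frame}, \code{z_um}, \code{y_um},
#'   \code{x_um}, optionally \code{intensity}.
#' @param channel channel label stored in the tracks.
#' @param max_displacement maximum frame-to-frame displacement (um).
#' @param max_gap maximum number of consecutive missing frames bridged.
#' @return list of [FocusTrack-class].
#' @export
linkTracks <- function(detections, channel = "green",
                       max_displacement = 0.8, max_gap = 2) {
  need <- c("frame", "z_um", "y_um", "x_um")
  stopifnot(all(need %in% names(detections)))
  if (!nrow(detections)) return(list())
  if (is.null(detections$intensity)) detections$intensity <- NA_real_
  detections <- detections[order(detections$frame), , drop = FALSE]

  tracks <- list()   # each: list(rows, last_pos, last_frame)
  active <- integer()
  P <- as.matrix(detections[, c("z_um", "y_um", "x_um")])
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    # retire heads whose gap can no longer be closed at this frame
    if (length(active))
      active <- active[f - vapply(tracks[active], `[[`, 0,
                                  "last_frame") <= max_gap + 1]
    rows_f <- which(detections$frame == f)
    assigned_det <- rep(FALSE, length(rows_f))
    if (length(active)) {
      cand <- expand.grid(ti = seq_along(active), di = seq_along(rows_f))
      cand$dist <- sqrt(rowSums(
        (do.call(rbind, lapply(active[cand$ti],
                               function(t) tracks[[t]]$last_pos)) -
           P[rows_f[cand$di], , drop = FALSE])^2))
      cand <- cand[cand$dist <= max_displacement, , drop = FALSE]
      if (nrow(cand)) {
        cand <- cand[order(cand$dist,
                           -detections$intensity[rows_f[cand$di]]), ,
                     drop = FALSE]
        used_t <- logical(length(active))
        for (r in seq_len(nrow(cand))) {
          ti <- cand$ti[r]; di <- cand$di[r]
          if (used_t[ti] || assigned_det[di]) next
          used_t[ti] <- TRUE; assigned_det[di] <- TRUE
          k <- active[ti]
          tracks[[k]]$rows <- c(tracks[[k]]$rows, rows_f[di])
          tracks[[k]]$last_pos <- P[rows_f[di], ]
          tracks[[k]]$last_frame <- f
        }
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(rows = rows_f[di],
                                           last_pos = P[rows_f[di], ],
                                           last_frame = f)
      active <- c(active, length(tracks))
    }
    active <- active[f - vapply(tracks[active], `[[`, 0, "last_frame") <= max_gap]
  }
  lapply(tracks, function(tr) {
    d <- detections[tr$rows, , drop = FALSE]
    span <- seq(min(d$frame), max(d$frame))
    new("FocusTrack", channel = channel, detections = d,
        gaps = as.numeric(setdiff(span, d$frame)))
  })
}

#' Pair green and red tracks into per-cell traces
#'
#' Each cell carries one green (lacO/lacI-GFP) and one red (tetO/tetR-
#' tdTomato) focus less than a micrometre apart. Tracks are paired by mutual
#' nearest median position within \code{pairing_radius}; unpaired tracks are
#' reported and excluded. Frames inside a track with no detection stay
#' missing (\code{NA}); gaps are never interpolated.
#'
#' @param tracks_green,tracks_red lists of [FocusTrack-class] from the same
#'   movie.
#' @param times full acquisition time grid (min); traces are aligned to it.
#' @param pairing_radius maximum green-red median distance (um).
#' @param min_length tracks with fewer detections are dropped up front
#'   (spurious detections rarely persist).
#' @return list with \code{traces} (list of [CellTrace-class], ids
#'   \code{cell_01}, ... ordered by position) and \code{unpaired}
#'   (data.frame describing excluded tracks).
#' @export
assembleCellTraces <- function(tracks_green, tracks_red, times,
                               pairing_radius = 1.0, min_length = 10) {
  keep <- function(trs) trs[vapply(trs, function(t) nrow(t@detections),
                                   0L) >= min_length]
  tg <- keep(tracks_green); tr <- keep(tracks_red)
  medpos <- function(trs) t(vapply(trs, function(t)
    c(median(t@detections$z_um), median(t@detections$y_um),
      median(t@detections$x_um)), numeric(3)))
  unpaired <- data.frame(channel = character(), n_detections = integer(),
                         y_um = numeric(), x_um = numeric())
  note_unpaired <- function(trs, idx) {
    if (!length(idx)) return(NULL)
    data.frame(channel = vapply(trs[idx], slot, "", "channel"),
               n_detections = vapply(trs[idx], function(t)
                 nrow(t@detections), 0L),
               y_um = vapply(trs[idx], function(t)
                 median(t@detections$y_um), 0),
               x_um = vapply(trs[idx], function(t)
                 median(t@detections$x_um), 0))
  }
  if (!length(tg) || !length(tr)) {
    unp <- rbind(note_unpaired(tg, seq_along(tg)),
                 note_unpaired(tr, seq_along(tr)))
    return(list(traces = list(),
                positions = data.frame(cell_id = character(),
                                       z_um = numeric(), y_um = numeric(),
                                       x_um = numeric()),
                unpaired = if (is.null(unp)) unpaired else unp))
  }
  pg <- medpos(tg); pr <- medpos(tr)
  d <- outer(seq_len(nrow(pg)), seq_len(nrow(pr)),
             Vectorize(function(i, j) sqrt(sum((pg[i, ] - pr[j, ])^2))))
  nn_g <- apply(d, 1, which.min)   # nearest red per green
  nn_r <- apply(d, 2, which.min)   # nearest green per red
  pairs <- which(nn_r[nn_g] == seq_along(nn_g) &
                 d[cbind(seq_along(nn_g), nn_g)] <= pairing_radius)
  if (anyDuplicated(nn_g[pairs]))
    stop("duplicate pairing: two green tracks claim one red track")

  ord <- order(pg[pairs, 2], pg[pairs, 3])  # stable ids: by y then x
  traces <- vector("list", length(pairs))
  positions <- data.frame(cell_id = sprintf("cell_%02d", seq_along(pairs)),
                          z_um = pg[pairs[ord], 1], y_um = pg[pairs[ord], 2],
                          x_um = pg[pairs[ord], 3])
  for (k in seq_along(pairs)) {
    gi <- pairs[ord][k]; ri <- nn_g[pairs[ord]][k]
    ig <- rep(NA_real_, length(times))
    ir <- rep(NA_real_, length(times))
    dg <- tg[[gi]]@detections; dr <- tr[[ri]]@detections
    ig[dg$frame] <- dg$intensity
    ir[dr$frame] <- dr$intensity
    traces[[k]] <- new("CellTrace", cell_id = sprintf("cell_%02d", k),
                       times = times, intensity_green = ig,
                       intensity_red = ir, provenance = "measured")
  }
  unp <- rbind(note_unpaired(tg, setdiff(seq_along(tg), pairs)),
               note_unpaired(tr, setdiff(seq_along(tr), unique(nn_g[pairs]))))
  list(traces = traces, positions = positions,
       unpaired = if (is.null(unp)) unpaired else unp)
}

#' Match measured traces to simulated ground-truth cells
#'
#' Assigns each assembled trace to the nearest ground-truth cell by its
#' median green-focus position (used to validate the pipeline against the
#' simulator's spot table).
#'
#' @param positions the \code{positions} table from [assembleCellTraces()].
#' @param spots ground-truth spot table of a simulated [MovieStack-class].
#' @param radius maximum match distance (um).
#' @return data.frame mapping trace \code{cell_id} to ground-truth
#'   \code{truth_id} (NA when unmatched).
#' @export
matchTracesToTruth <- function(positions, spots, radius = 1.0) {
  g <- spots[spots$channel == "green", , drop = FALSE]
  truth_id <- vapply(seq_len(nrow(positions)), function(i) {
    d <- sqrt((g$z_um - positions$z_um[i])^2 +
              (g$y_um - positions$y_um[i])^2 +
              (g$x_um - positions$x_um[i])^2)
    if (length(d) && min(d) <= radius) g$cell_id[which.min(d)]
    else NA_character_
  }, "")
  data.frame(cell_id = positions$cell_id, truth_id = truth_id)
}
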