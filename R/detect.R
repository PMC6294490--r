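# 3D spot detection and quantification (the detection stage of the foci
# pipeline).
# Detection runs on a band-passed (difference-of-Gaussians) volume; intensity
# is always measured on the raw volume, because band-passing distorts
# integrated intensities.

#' Detect diffraction-limited spots in a 3D volume
#'
#' Difference-of-Gaussians band-pass at the expected spot scale, 26-neighbour
#' local maxima, a robust threshold at \code{k_sigma} times the median
#' absolute deviation of the band-passed volume, and sub-voxel localization
#' by intensity-weighted centre of mass of the (positive) band-pass response
#' in a small neighbourhood. Co-detected spots closer than
#' \code{merge_radius} are merged (response-weighted), because a duplicating
#' locus can transiently resolve into sister foci whose total intensity is
#' what the assay reads.
#'
#' @param volume 3D array (z, y, x) of intensities.
#' @param voxel_size physical voxel size c(z, y, x) in um; required, because
#'   the z-step differs from the pixel size and the filter must be
#'   anisotropy-aware.
#' @param dog_sigma_small,dog_sigma_large band-pass sigmas c(xy, z) in um;
#'   \code{dog_sigma_large} defaults to twice the small sigma.
#' @param k_sigma detection threshold in robust noise units.
#' @param merge_radius merge co-detections closer than this (um).
#' @param edge_margin voxels c(z, y, x) at the volume boundary excluded from
#'   candidate maxima: the band-pass variance is inflated there by the
#'   boundary condition, and an edge spot cannot be quantified anyway.
#' @return data.frame with one row per detection: 0-based fractional voxel
#'   coordinates \code{z}, \code{y}, \code{x}; physical positions
#'   \code{z_um}, \code{y_um}, \code{x_um}; and the band-pass \code{response}.
#' @examples
#' vol <- renderSpotVolume(c(12, 40, 40), c(0.7, 0.107, 0.107),
#'                         center_um = c(4.2, 2.1, 2.1), amplitude = 3000)
#' detectSpots(vol + 1, voxel_size = c(0.7, 0.107, 0.107))
#' @export
detectSpots <- function(volume, voxel_size = NULL,
                        dog_sigma_small = c(0.15, 0.6),
                        dog_sigma_large = NULL, k_sigma = 5,
                        merge_radius = 0.5, edge_margin = c(2, 5, 5)) {
  if (is.null(voxel_size) || length(voxel_size) != 3)
    stop("voxel_size c(z, y, x) in um is required (z anisotropy)")
  if (length(dim(volume)) != 3) stop("volume must be a 3D array (z, y, x)")
  if (any(!is.finite(volume))) stop("volume must be finite")
  if (is.null(dog_sigma_large)) dog_sigma_large <- 2 * dog_sigma_small
  dims <- dim(volume)
  sv <- function(s) c(s[2] / voxel_size[1], s[1] / voxel_size[2],
                      s[1] / voxel_size[3])  # (z, y, x) in voxels
  ss <- sv(dog_sigma_small); sl <- sv(dog_sigma_large)
  dog <- gaussBlur3D(as.numeric(volume), as.integer(dims),
                     ss[1], ss[2], ss[3]) -
         gaussBlur3D(as.numeric(volume), as.integer(dims),
                     sl[1], sl[2], sl[3])
  dim(dog) <- dims
  noise_scale <- mad(dog)
  peaks <- localMax3D(as.numeric(dog), as.integer(dims)) &
    (dog > k_sigma * noise_scale)
  dim(peaks) <- dims
  idx <- which(peaks, arr.ind = TRUE)  # 1-based (z, y, x)
  if (nrow(idx)) {
    inside <- rep(TRUE, nrow(idx))
    for (a in 1:3)
      inside <- inside & idx[, a] > edge_margin[a] &
        idx[, a] <= dims[a] - edge_margin[a]
    idx <- idx[inside, , drop = FALSE]
  }
  if (nrow(idx) == 0) {
    return(data.frame(z = numeric(), y = numeric(), x = numeric(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      response = numeric()))
  }
  r_nb <- pmax(1, ceiling(2 * ss))
  pos <- matrix(0, nrow(idx), 3)
  resp <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    rng <- lapply(1:3, function(a)
      max(1, idx[i, a] - r_nb[a]):min(dims[a], idx[i, a] + r_nb[a]))
    nb <- dog[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    w <- pmax(nb, 0)
    grid <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
    sw <- sum(w)
    pos[i, ] <- if (sw > 0) colSums(as.matrix(grid) * as.numeric(w)) / sw
                else idx[i, ]
    resp[i] <- dog[idx[i, 1], idx[i, 2], idx[i, 3]]
  }
  pos <- pos - 1  # 0-based fractional voxel coordinates
  # merge near-coincident detections (sister foci): response-weighted
  repeat {
    if (nrow(pos) < 2) break
    um <- sweep(pos + 0.5, 2, voxel_size, `*`)
    d <- as.matrix(dist(um))
    diag(d) <- Inf
    mn <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[mn[1], mn[2]] >= merge_radius) break
    i <- mn[1]; j <- mn[2]
    wi <- resp[i] / (resp[i] + resp[j])
    pos[i, ] <- wi * pos[i, ] + (1 - wi) * pos[j, ]
    resp[i] <- resp[i] + resp[j]
    pos <- pos[-j, , drop = FALSE]
    resp <- resp[-j]
  }
  um <- sweep(pos + 0.5, 2, voxel_size, `*`)
  out <- data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3],
                    z_um = um[, 1], y_um = um[, 2], x_um = um[, 3],
                    response = resp)
  out[order(-out$response), , drop = FALSE]
}

#' Background-subtracted integrated spot intensity
#'
#' Sums the raw volume over an anisotropy-scaled core ellipsoid (z semi-axis
#' stretched by \code{z_scale}, matching the elongated PSF) and subtracts the
#' median of a surrounding shell times the core voxel count. The result can
#' be negative on noise; QC decides downstream. A shell clipped by the volume
#' edge flags the measurement.
#'
#' @param volume raw 3D array (z, y, x).
#' @param center_um spot centre c(z, y, x) in um.
#' @param voxel_size voxel size c(z, y, x) in um.
#' @param r_core core radius (um, lateral); the core is an ellipsoid with z
#'   semi-axis \code{r_core * z_scale}.
#' @param r_bg_inner,r_bg_outer background shell radii (um, lateral).
#' @param z_scale axial stretch of core and shell.
#' @return list with \code{intensity} (photons), \code{background} (median
#'   shell level per voxel), \code{n_core} and \code{clipped}.
#' @export
measureSpotIntensity <- function(volume, center_um, voxel_size,
                                 r_core = 0.5, r_bg_inner = 0.7,
                                 r_bg_outer = 1.0, z_scale = 3) {
  stopifnot(length(dim(volume)) == 3, length(center_um) == 3,
            length(voxel_size) == 3, r_core < r_bg_inner,
            r_bg_inner < r_bg_outer)
  dims <- dim(volume)
  half <- c(r_bg_outer * z_scale, r_bg_outer, r_bg_outer)
  lo <- floor(center_um / voxel_size - 0.5 - half / voxel_size)
  hi <- ceiling(center_um / voxel_size - 0.5 + half / voxel_size)
  clipped <- any(lo < 0) || any(hi > dims - 1)
  lo <- pmax(lo, 0); hi <- pmin(hi, dims - 1)
  rng <- lapply(1:3, function(a) lo[a]:hi[a])
  sub <- volume[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1, drop = FALSE]
  cz <- (rng[[1]] + 0.5) * voxel_size[1] - center_um[1]
  cy <- (rng[[2]] + 0.5) * voxel_size[2] - center_um[2]
  cx <- (rng[[3]] + 0.5) * voxel_size[3] - center_um[3]
  dz2 <- (cz / z_scale)^2
  dn <- sqrt(outer(outer(dz2, cy^2, `+`), cx^2, `+`))
  core <- dn <= r_core
  shell <- dn > r_bg_inner & dn <= r_bg_outer
  n_core <- sum(core)
  if (n_core == 0 || sum(shell) == 0) {
    return(list(intensity = NA_real_, background = NA_real_,
                n_core = n_core, clipped = TRUE))
  }
  bg <- median(sub[shell])
  list(intensity = sum(sub[core]) - bg * n_core, background = bg,
       n_core = n_core, clipped = clipped)
}

#' Detect and quantify spots in every frame and channel of a movie
#'
#' Per-frame processing is stateless (frames can be processed in any order);
#' linking happens afterwards in [linkTracks()].
#'
#' @param movie a [MovieStack-class].
#' @param ... passed to [detectSpots()].
#' @param r_core,r_bg_inner,r_bg_outer,z_scale passed to
#'   [measureSpotIntensity()].
#' @param verbose print per-frame detection counts.
#' @return data.frame of detections with \code{frame}, \code{channel},
#'   positions, \code{response}, background-subtracted \code{intensity} and
#'   \code{clipped}.
#' @export
detectSpotsMovie <- function(movie, ..., r_core = 0.5, r_bg_inner = 0.7,
                             r_bg_outer = 1.0, z_scale = 3, verbose = FALSE) {
  stopifnot(is(movie, "MovieStack"))
  m <- movie@metadata
  vs <- c(m@z_step, m@pixel_size, m@pixel_size)
  out <- vector("list", m@n_frames * 2)
  k <- 0
  for (t in seq_len(m@n_frames)) {
    for (ch in 1:2) {
      vol <- array(movie@data[t, ch, , , ], dim(movie@data)[3:5])
      det <- detectSpots(vol, voxel_size = vs, ...)
      if (verbose)
        message(sprintf("frame %d %s: %d spots", t,
                        c("green", "red")[ch], nrow(det)))
      if (nrow(det)) {
        meas <- lapply(seq_len(nrow(det)), function(i)
          measureSpotIntensity(vol, c(det$z_um[i], det$y_um[i], det$x_um[i]),
                               vs, r_core, r_bg_inner, r_bg_outer, z_scale))
        det$intensity <- vapply(meas, `[[`, 0, "intensity")
        det$clipped <- vapply(meas, `[[`, TRUE, "clipped")
        det$frame <- t
        det$channel <- c("green", "red")[ch]
        k <- k + 1
        out[[k]] <- det
      }
    }
  }
  if (k == 0) {
    return(data.frame(z = numeric(), y = numeric(), x = numeric(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      response = numeric(), intensity = numeric(),
                      clipped = logical(), frame = integer(),
                      channel = character()))
  }
  do.call(rbind, out[seq_len(k)])
}
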