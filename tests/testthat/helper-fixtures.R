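# Shared fixtures and independent oracles, built in code at test time.

VOX <- c(0.7, 0.107, 0.107)  # default voxel size (z, y, x) um

# peak voxel value of a unit-amplitude integrated Gaussian spot
peakPerAmplitude <- function(voxel_size = VOX, sigma_xy = 0.13,
                             sigma_z = 0.6) {
  prod(voxel_size / (sqrt(2 * pi) * c(sigma_z, sigma_xy, sigma_xy)))
}

# a noisy volume with spots at given (z, y, x) um centres and a given peak SNR
makeSpotVolume <- function(dims, centers, snr, sigma_n = 10, bg = 100,
                           voxel_size = VOX) {
  amp <- snr * sigma_n / peakPerAmplitude(voxel_size)
  vol <- array(0, dims)
  for (i in seq_len(nrow(centers)))
    vol <- vol + renderSpotVolume(dims, voxel_size, centers[i, ], amp)
  vol + bg + array(rnorm(prod(dims), sd = sigma_n), dims)
}

# exhaustive minimal-cost injective assignment of prev spots to next spots
# under a distance cutoff; oracle for the greedy tracker on <= 3 spots
bruteForceAssign <- function(prev, nxt, max_displacement) {
  np <- nrow(prev); nn <- nrow(nxt)
  d <- outer(seq_len(np), seq_len(nn), Vectorize(function(i, j)
    sqrt(sum((prev[i, ] - nxt[j, ])^2))))
  best <- NULL; best_cost <- Inf; best_n <- -1
  # enumerate all partial injective maps prev -> nxt
  choices <- c(0, seq_len(nn))  # 0 = unmatched
  grids <- do.call(expand.grid, rep(list(choices), np))
  for (r in seq_len(nrow(grids))) {
    a <- as.numeric(grids[r, ])
    m <- a[a > 0]
    if (anyDuplicated(m)) next
    if (any(a > 0 & d[cbind(seq_len(np), pmax(a, 1))] > max_displacement))
      next
    cost <- sum(d[cbind(which(a > 0), a[a > 0])])
    nmatch <- sum(a > 0)
    # maximise matches, then minimise cost (a tracker must not drop links)
    if (nmatch > best_n || (nmatch == best_n && cost < best_cost)) {
      best <- a; best_cost <- cost; best_n <- nmatch
    }
  }
  best
}

# assignment realised by linkTracks() on a two-frame detection set
greedyAssign <- function(prev, nxt, max_displacement) {
  det <- data.frame(
    frame = rep(1:2, c(nrow(prev), nrow(nxt))),
    z_um = c(prev[, 1], nxt[, 1]),
    y_um = c(prev[, 2], nxt[, 2]),
    x_um = c(prev[, 3], nxt[, 3]),
    intensity = 1)
  tracks <- linkTracks(det, max_displacement = max_displacement, max_gap = 0)
  a <- rep(0, nrow(prev))
  for (tr in tracks) {
    dd <- tr@detections
    if (nrow(dd) == 2) {
      i <- which(prev[, 1] == dd$z_um[1] & prev[, 2] == dd$y_um[1] &
                 prev[, 3] == dd$x_um[1])
      j <- which(nxt[, 1] == dd$z_um[2] & nxt[, 2] == dd$y_um[2] &
                 nxt[, 3] == dd$x_um[2])
      a[i] <- j
    }
  }
  a
}

# E[1/v] for the log-normal fork-speed law, by numerical quadrature
# (independent of the closed form used nowhere in the package)
eInvSpeed <- function(mean_v, cv) {
  if (cv == 0) return(1 / mean_v)
  s2 <- log(1 + cv^2)
  mu <- log(mean_v) - s2 / 2
  integrate(function(v) dlnorm(v, mu, sqrt(s2)) / v,
            lower = 0, upper = Inf, rel.tol = 1e-10)$value
}
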