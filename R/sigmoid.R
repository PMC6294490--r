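#' Fit the bleach-aware logistic step to a focus intensity trace
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt) of
#' I(t) = exp(-kb t) (B + A / (1 + exp(-(t - t_mid)/tau))).
#' The fitted \code{t_mid} is the mid-rise point used for replication
#' timing. Photobleaching is estimated inside the fit rather than removed by
#' pre-detrending, which would bias the step. Initialization: B from the
#' median of the first quartile of frames, A from the last quartile, t_mid at
#' the maximum of the smoothed first difference, tau at three frame
#' intervals, kb at 0. Bounds: B > 0, A >= 0, t_mid within 10 min of the
#' observation window, tau > 0, kb >= 0.
#'
#' @param times acquisition times (min); missing intensities are allowed and
#'   ignored.
#' @param intensities focus intensities.
#' @param channel label stored in the result.
#' @param fix_bleach fit with the bleaching rate fixed at 0.
#' @return a [SigmoidFit-class]; non-convergence sets
#'   \code{converged = FALSE} (never an error).
#' @examples
#' t <- 0:179
#' y <- sigmoidTraceModel(t, 100, 100, 60, 2)
#' fitIntensitySigmoid(t, y)
#' @export
fitIntensitySigmoid <- function(times, intensities, channel = "green",
                                fix_bleach = FALSE) {
  stopifnot(length(times) == length(intensities))
  ok <- is.finite(times) & is.finite(intensities)
  t <- times[ok]; y <- intensities[ok]
  n <- length(t)
  unconverged <- function() new("SigmoidFit", channel = channel,
    B = NA_real_, A = NA_real_, t_mid = NA_real_, tau = NA_real_,
    bleach_rate = NA_real_, r_squared = NA_real_, converged = FALSE,
    t_range = if (n) range(t) else c(NA_real_, NA_real_))
  if (n < 8) return(unconverged())
  o <- order(t); t <- t[o]; y <- y[o]

  nq <- max(3L, floor(n / 4))
  scale <- max(abs(y), 1)
  B0 <- max(median(y[seq_len(nq)]), 1e-6 * scale)
  A0 <- max(median(y[seq(n - nq + 1, n)]) - B0, 1e-6 * scale)
  d <- diff(y)
  ds <- stats::filter(d, rep(1 / 5, 5), sides = 2)
  ds[is.na(ds)] <- -Inf
  tm0 <- t[which.max(ds)]
  dt <- median(diff(t))
  tau0 <- 3 * dt
  span <- t[n] - t[1]

  lower <- c(B = 1e-9 * scale, A = 0, tm = t[1] - 10, tau = 1e-3,
             kb = 0)
  upper <- c(B = Inf, A = Inf, tm = t[n] + 10, tau = span, kb = 0.2)
  if (fix_bleach) upper["kb"] <- 1e-12
  model <- function(p) exp(-p[5] * t) *
    (p[1] + p[2] / (1 + exp(-(t - p[3]) / p[4])))
  do_fit <- function(start) {
    out <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = function(p) y - model(p),
                         lower = lower, upper = upper,
                         control = nls.lm.control(maxiter = 400,
                                                  ftol = 1e-14,
                                                  ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:3) || any(!is.finite(out$par)))
      return(NULL)
    out
  }
  # a small ladder of starts: the data-driven one, then a doubling prior
  fit <- do_fit(c(B = B0, A = A0, tm = tm0, tau = tau0, kb = 1e-4))
  if (is.null(fit))
    fit <- do_fit(c(B = B0, A = B0, tm = tm0, tau = tau0, kb = 1e-4))
  if (is.null(fit))
    fit <- do_fit(c(B = B0, A = B0, tm = (t[1] + t[n]) / 2,
                    tau = 2 * tau0, kb = 1e-4))
  if (is.null(fit)) return(unconverged())
  p <- fit$par
  ss_res <- sum((y - model(p))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 1e-12 * scale^2) 1 - ss_res / ss_tot else NA_real_
  new("SigmoidFit", channel = channel, B = unname(p["B"]),
      A = unname(p["A"]), t_mid = unname(p["tm"]), tau = unname(p["tau"]),
      bleach_rate = unname(p["kb"]), r_squared = min(r2, 1),
      converged = TRUE, t_range = c(t[1], t[n]))
}
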