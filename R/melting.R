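# Two-state van 't Hoff analysis of UV melting curves (A295). A folded
# G-quadruplex loses its 295-nm hyperchromicity on unfolding; the normalized
# signal approximates the folded fraction theta(T).

R_KCAL <- 0.0019872041  # gas constant, kcal / (mol K)

#' Two-state folded fraction
#'
#' theta(T) = 1 / (1 + exp(-(dH/R) (1/T_K - 1/Tm_K))), the unimolecular
#' two-state (all-or-none) equilibrium with the entropy fixed by the midpoint
#' condition dS = dH/Tm_K. theta(Tm) = 0.5 exactly and theta is strictly
#' decreasing in T for dH > 0.
#'
#' @param temps temperatures (deg C).
#' @param Tm melting temperature (deg C).
#' @param dH van 't Hoff unfolding enthalpy (kcal/mol).
#' @return folded fractions.
#' @export
twoStateTheta <- function(temps, Tm, dH) {
  TK <- temps + 273.15
  TmK <- Tm + 273.15
  1 / (1 + exp(-(dH / R_KCAL) * (1 / TK - 1 / TmK)))
}

#' Simulate a normalized melting curve
#'
#' Two-state signal plus Gaussian noise on the standard acquisition grid:
#' starting in the 14-16 deg C range with 2 deg C increments.
#'
#' @param Tm melting temperature (deg C).
#' @param dH unfolding enthalpy (kcal/mol), > 0.
#' @param temps temperature grid (deg C), strictly increasing.
#' @param noise_sd Gaussian noise sd (normalized units).
#' @param label oligo name.
#' @param seed RNG seed; \code{NULL} uses the caller's RNG state.
#' @return a [MeltingCurve-class].
#' @export
simulateMeltingCurve <- function(Tm, dH, temps = seq(15, 95, by = 2),
                                 noise_sd = 0, label = "G4", seed = NULL) {
  if (!(dH > 0)) stop("dH must be > 0 (unfolding enthalpy convention)")
  if (length(temps) > 1 && any(diff(temps) <= 0))
    stop("temps must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  y <- twoStateTheta(temps, Tm, dH)
  if (noise_sd > 0) y <- y + rnorm(length(temps), sd = noise_sd)
  new("MeltingCurve", temps = temps, signal = y, label = label)
}

#' Normalize a raw A295 melting curve
#'
#' Linear baselines are fitted to the lowest- and highest-temperature
#' quartiles of the points (folded and unfolded states respectively); the
#' normalized signal is (raw - unfolded)/(folded - unfolded), i.e. an
#' apparent folded fraction. Values outside [-0.1, 1.1] are reported with a
#' warning but not clamped.
#'
#' @param raw_temps temperatures (deg C), strictly increasing, >= 8 points.
#' @param raw_A295 raw absorbance at 295 nm.
#' @param label oligo name.
#' @return a [MeltingCurve-class].
#' @export
normalizeMelting <- function(raw_temps, raw_A295, label = "G4") {
  n <- length(raw_temps)
  if (n < 8) stop("at least 8 points are required")
  stopifnot(length(raw_A295) == n, all(is.finite(raw_A295)))
  if (any(diff(raw_temps) <= 0)) stop("temps must be strictly increasing")
  k <- max(2L, floor(n / 4))
  lo <- seq_len(k); hi <- seq(n - k + 1, n)
  fit_f <- lm(y ~ t, data.frame(t = raw_temps[lo], y = raw_A295[lo]))
  fit_u <- lm(y ~ t, data.frame(t = raw_temps[hi], y = raw_A295[hi]))
  base_f <- unname(predict(fit_f, data.frame(t = raw_temps)))
  base_u <- unname(predict(fit_u, data.frame(t = raw_temps)))
  denom <- base_f - base_u
  if (any(abs(denom) < 1e-12) || any(denom * denom[1] <= 0))
    stop("degenerate baselines: folded and unfolded baselines coincide or cross")
  y <- (raw_A295 - base_u) / denom
  out <- sum(y < -0.1 | y > 1.1)
  if (out > 0)
    warning(out, " normalized point(s) outside [-0.1, 1.1]")
  new("MeltingCurve", temps = raw_temps, signal = y, label = label)
}

#' Fit the two-state van 't Hoff model to a normalized melting curve
#'
#' Least-squares fit of [twoStateTheta()] in absolute temperature,
#' optionally with residual linear baselines for the folded and unfolded
#' states. Initialization: Tm at the 0.5 crossing of the signal, dH at
#' 40 kcal/mol (sign from the curve direction). A transition not bracketed
#' by the data (the signal never crosses 0.5) gives
#' \code{converged = FALSE} with a \code{"transition_not_bracketed"} flag; a
#' refolding-type (increasing) curve fits with dH < 0 and is flagged
#' \code{"non_standard_increasing"}.
#'
#' @param curve a [MeltingCurve-class] (normalized).
#' @param baselines also fit residual linear baselines.
#' @return a [MeltingFit-class].
#' @examples
#' cv <- simulateMeltingCurve(Tm = 55, dH = 45)
#' fitTwoStateMelting(cv)
#' @export
fitTwoStateMelting <- function(curve, baselines = FALSE) {
  stopifnot(is(curve, "MeltingCurve"))
  temps <- curve@temps; y <- curve@signal
  failed <- function(flags) new("MeltingFit", Tm = NA_real_,
    dH_vH = NA_real_, dS_vH = NA_real_, baseline = c(0, 0, 1, 0),
    r_squared = NA_real_, converged = FALSE, flags = flags)
  s <- sign(y - 0.5)
  cross <- which(s[-1] * s[-length(s)] <= 0)
  if (!length(cross) || all(s > 0) || all(s < 0))
    return(failed("transition_not_bracketed"))
  i <- cross[1]
  tm0 <- temps[i] + (0.5 - y[i]) * (temps[i + 1] - temps[i]) /
    (y[i + 1] - y[i])
  decreasing <- mean(y[seq_len(i)]) > mean(y[seq(i + 1, length(y))])
  dh0 <- if (decreasing) 40 else -40

  dat <- data.frame(t = temps, y = y)
  fit <- tryCatch({
    if (baselines) {
      nlsLM(y ~ (u0 + u1 * t) + ((f0 + f1 * t) - (u0 + u1 * t)) /
              (1 + exp(-(dH / 0.0019872041) *
                       (1 / (t + 273.15) - 1 / (Tm + 273.15)))),
            data = dat,
            start = list(Tm = tm0, dH = dh0, u0 = 0, u1 = 0, f0 = 1, f1 = 0),
            lower = c(Tm = min(temps) - 20, dH = -500, u0 = -Inf, u1 = -Inf,
                      f0 = -Inf, f1 = -Inf),
            upper = c(Tm = max(temps) + 20, dH = 500, u0 = Inf, u1 = Inf,
                      f0 = Inf, f1 = Inf),
            control = nls.lm.control(maxiter = 400, ftol = 1e-14))
    } else {
      nlsLM(y ~ 1 / (1 + exp(-(dH / 0.0019872041) *
                             (1 / (t + 273.15) - 1 / (Tm + 273.15)))),
            data = dat, start = list(Tm = tm0, dH = dh0),
            lower = c(Tm = min(temps) - 20, dH = -500),
            upper = c(Tm = max(temps) + 20, dH = 500),
            control = nls.lm.control(maxiter = 400, ftol = 1e-14))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed("fit_failed"))
  p <- coef(fit)
  flags <- character()
  if (p["dH"] < 0) flags <- c(flags, "non_standard_increasing")
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  bl <- if (baselines) unname(p[c("u0", "u1", "f0", "f1")]) else c(0, 0, 1, 0)
  new("MeltingFit", Tm = unname(p["Tm"]), dH_vH = unname(p["dH"]),
      dS_vH = unname(p["dH"]) / (unname(p["Tm"]) + 273.15),
      baseline = bl, r_squared = min(r2, 1), converged = TRUE,
      flags = flags)
}
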