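#' Construct a simulation scenario
#'
#' Default fork speed (1.5 kb/min) gives a 20-min delay over the nominal
#' 30 kb interval; the 25% cell-to-cell CV reproduces the spread of
#' single-cell replication delays seen in wild-type cohorts. Pauses model a
#' folded obstacle: a cell is "paused" with probability
#' \code{folded_fraction} (the folded/unfolded subpopulation structure of a
#' two-state obstacle) and then incurs an exponential (or fixed) extra delay
#' of mean \code{pause_mean} minutes.
#'
#' @param label scenario/strain name.
#' @param fork_speed_mean mean replication fork speed (kb/min).
#' @param fork_speed_cv cell-to-cell coefficient of variation of fork speed.
#' @param pause_mean expected obstacle pause (min) in paused cells.
#' @param folded_fraction probability the obstacle is folded in a given cell.
#' @param n_cells number of cells.
#' @param seed RNG seed (NA = use the caller's RNG state).
#' @param firing_time_mean,firing_time_sd normal origin-firing offset (min
#'   after acquisition start).
#' @param pause_model \code{"exponential"} or \code{"fixed"}.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(label = "wt", fork_speed_mean = 1.5,
                           fork_speed_cv = 0.25, pause_mean = 0,
                           folded_fraction = 0, n_cells = 25,
                           seed = NA_real_, firing_time_mean = 30,
                           firing_time_sd = 5,
                           pause_model = c("exponential", "fixed")) {
  new("ScenarioConfig", label = label,
      fork_speed_mean = fork_speed_mean, fork_speed_cv = fork_speed_cv,
      pause_mean = pause_mean, folded_fraction = folded_fraction,
      n_cells = n_cells, seed = as.numeric(seed),
      firing_time_mean = firing_time_mean, firing_time_sd = firing_time_sd,
      pause_model = match.arg(pause_model))
}

#' Sample per-cell ground-truth replication kinetics
#'
#' Each cell draws a fork speed v from a log-normal with the configured mean
#' and CV; the proximal array replicates at
#' firing offset + (origin-to-mid-array-1 distance)/v, and the distal array
#' after a further mid-to-mid distance / v. If the layout carries an obstacle,
#' a cell is paused with probability \code{folded_fraction} and adds a pause
#' drawn from Exponential(mean = pause_mean) (or exactly \code{pause_mean}
#' under \code{pause_model = "fixed"}) to the delay.
#'
#' @param layout a [LocusLayout-class].
#' @param scenario a [ScenarioConfig-class].
#' @return data.frame with one row per cell: \code{cell_id},
#'   \code{fork_speed} (kb/min), \code{firing_time}, \code{t_rep_array1},
#'   \code{t_rep_array2}, \code{delta_t_true} (min) and \code{paused}.
#'   \code{delta_t_true = t_rep_array2 - t_rep_array1} always holds.
#' @examples
#' gt <- sampleCellKinetics(nominalLocusLayout(),
#'                          scenarioConfig(n_cells = 5, seed = 1))
#' stopifnot(all.equal(gt$delta_t_true, gt$t_rep_array2 - gt$t_rep_array1))
#' @export
sampleCellKinetics <- function(layout, scenario) {
  stopifnot(is(layout, "LocusLayout"), is(scenario, "ScenarioConfig"))
  validObject(layout); validObject(scenario)
  if (!is.na(scenario@seed)) set.seed(scenario@seed)
  n <- as.integer(scenario@n_cells)
  if (n == 0) {
    return(data.frame(cell_id = character(), fork_speed = numeric(),
                      firing_time = numeric(), t_rep_array1 = numeric(),
                      t_rep_array2 = numeric(), delta_t_true = numeric(),
                      paused = logical()))
  }
  geom <- attr(locusGeometry(layout), "exact")
  # origin to the midpoint of array 1 (array 1 extends toward the origin)
  d1 <- (layout@array1_pos - layout@origin_pos) / 1000 - layout@array_len / 2
  if (d1 <= 0) stop("origin must lie upstream of the whole of array 1")

  cv <- scenario@fork_speed_cv
  if (cv > 0) {
    s2 <- log(1 + cv^2)
    v <- rlnorm(n, meanlog = log(scenario@fork_speed_mean) - s2 / 2,
                sdlog = sqrt(s2))
  } else {
    v <- rep(scenario@fork_speed_mean, n)
  }
  firing <- pmax(0, rnorm(n, scenario@firing_time_mean, scenario@firing_time_sd))
  has_obstacle <- !is.na(layout@obstacle_pos)
  paused <- has_obstacle & scenario@pause_mean > 0 &
    runif(n) < scenario@folded_fraction
  pause <- numeric(n)
  if (any(paused)) {
    pause[paused] <- if (scenario@pause_model == "exponential")
      rexp(sum(paused), rate = 1 / scenario@pause_mean)
    else scenario@pause_mean
  }
  t1 <- firing + d1 / v
  delta <- geom$mid_to_mid_kb / v + pause
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
             fork_speed = v, firing_time = firing,
             t_rep_array1 = t1, t_rep_array2 = t1 + delta,
             delta_t_true = delta, paused = paused)
}
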