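# Cohort statistics: per-strain summaries, fold-changes, and the two-sample
# Monte Carlo resampling significance test.

#' Summarize a cohort of QC-passed replication events
#'
#' @param events QC-passed events table (rows = cells), or a numeric vector
#'   of per-cell delta_t values.
#' @param label strain/scenario name.
#' @param bin_width histogram bin width (min); bins are anchored at 0.
#' @return a [CohortResult-class]: n, mean delta_t, SEM (sample sd over
#'   sqrt(n)), mean per-cell rate, and the histogram.
#' @examples
#' summarizeCohort(data.frame(delta_t = c(10, 20, 30),
#'                            rate = 30 / c(10, 20, 30)), "demo")
#' @export
summarizeCohort <- function(events, label = "cohort", bin_width = 2) {
  if (is.numeric(events)) events <- data.frame(delta_t = events,
                                               rate = NA_real_)
  d <- events$delta_t
  if (length(d) < 2) stop("a cohort needs at least 2 events")
  if (any(!is.finite(d))) stop("delta_t must be finite for all events")
  lo <- min(0, floor(min(d) / bin_width) * bin_width)
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= max(d)) hi <- hi + bin_width   # right-open bins
  breaks <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(d, breaks = breaks, right = FALSE,
                           plot = FALSE)$counts
  new("CohortResult", label = label, n = length(d),
      mean_delta_t = mean(d), sem = sd(d) / sqrt(length(d)),
      mean_rate = mean(events$rate, na.rm = TRUE),
      breaks = breaks, counts = counts)
}

#' Two-sample Monte Carlo resampling significance test
#'
#' Permutation implementation: the per-cell delta_t values of the two
#' cohorts are pooled; labels are reshuffled preserving group sizes for
#' \code{n_iterations} iterations, recomputing the (absolute) difference of
#' means; p = (number of resampled statistics >= observed + 1) /
#' (n_iterations + 1), so p is never exactly 0. The published analyses use
#' 1,000,000 iterations, which is the default. A pooled-bootstrap variant
#' (both groups redrawn with replacement from the pool) is available for
#' sensitivity analysis.
#'
#' @param a,b numeric vectors of per-cell delta_t values (or events tables
#'   with a \code{delta_t} column).
#' @param n_iterations resampling iterations (>= 1).
#' @param seed RNG seed; \code{NULL} uses the caller's RNG state.
#' @param two_sided use the absolute difference of means.
#' @param method \code{"permutation"} (default) or \code{"bootstrap"}.
#' @return a [ResamplingTestResult-class].
#' @examples
#' resamplingTest(c(1, 2), c(3, 4), n_iterations = 1e4, seed = 1)  # p ~ 1/3
#' @export
resamplingTest <- function(a, b, n_iterations = 1e6, seed = NULL,
                           two_sided = TRUE,
                           method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (is.data.frame(a)) a <- a$delta_t
  if (is.data.frame(b)) b <- b$delta_t
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(a) - mean(b)
  obs_stat <- if (two_sided) abs(obs) else obs
  if (two_sided) {
    # canonical form: sorted pool, smaller group resampled — |mean diff| is
    # invariant under complementation, so a label swap gives identical p
    pool <- sort(c(a, b))
    k <- min(length(a), length(b))
  } else {
    pool <- c(a, b)
    k <- length(a)
  }
  cnt <- permTestCount(pool, k, n_iterations, obs_stat,
                       two_sided, method == "bootstrap")
  new("ResamplingTestResult", observed_diff = obs,
      n_iterations = n_iterations, p_value = (cnt + 1) / (n_iterations + 1),
      n_exceed = cnt, two_sided = two_sided,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      method = method)
}

#' Significance stars at the figure-legend thresholds
#'
#' Thresholds 0.05, 0.005, 0.0005 and 0.00005 map to one to four stars.
#'
#' @param p p-value(s).
#' @return character vector of \code{"ns"} to \code{"****"}.
#' @export
starSignificance <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi < 0.00005) "****" else if (pi < 0.0005) "***"
    else if (pi < 0.005) "**" else if (pi < 0.05) "*" else "ns"
  }, "")
}

#' Fold-change between two cohorts
#'
#' The delta_t ratio test/reference equals the fold-decrease in replication
#' rate (rate is distance over delta_t, with a common distance). The percent
#' reduction in rate is 100 (1 - 1/ratio): a 2-fold slowdown is a 50%
#' reduction, a 1.5-fold slowdown 33%.
#'
#' @param reference,test [CohortResult-class] objects with positive means.
#' @return list with \code{delta_t_ratio}, \code{rate_fold_decrease} and
#'   \code{percent_rate_reduction}.
#' @export
foldChange <- function(reference, test) {
  stopifnot(is(reference, "CohortResult"), is(test, "CohortResult"))
  if (!(reference@mean_delta_t > 0) || !(test@mean_delta_t > 0))
    stop("fold-change requires positive cohort means")
  ratio <- test@mean_delta_t / reference@mean_delta_t
  list(delta_t_ratio = ratio, rate_fold_decrease = ratio,
       percent_rate_reduction = 100 * (1 - 1 / ratio))
}

#' Bootstrap confidence interval for a cohort delta_t ratio
#'
#' Resamples cells with replacement within each cohort and returns the
#' percentile interval of the ratio of means.
#'
#' @param delta_ref,delta_test per-cell delta_t vectors (or events tables).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed; \code{NULL} uses the caller's RNG state.
#' @return named vector: \code{estimate}, \code{lower}, \code{upper}.
#' @export
bootstrapRatioCI <- function(delta_ref, delta_test, n_boot = 2000,
                             conf = 0.95, seed = NULL) {
  if (is.data.frame(delta_ref)) delta_ref <- delta_ref$delta_t
  if (is.data.frame(delta_test)) delta_test <- delta_test$delta_t
  if (!is.null(seed)) set.seed(seed)
  ratios <- vapply(seq_len(n_boot), function(i)
    mean(sample(delta_test, replace = TRUE)) /
      mean(sample(delta_ref, replace = TRUE)), 0)
  q <- quantile(ratios, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(estimate = mean(delta_test) / mean(delta_ref),
    lower = q[1], upper = q[2])
}

#' Compare several cohorts against a reference
#'
#' Summaries, pairwise resampling tests against the reference cohort, star
#' notation at the legend thresholds, and fold-changes.
#'
#' @param events_list named list of QC-passed events tables (or delta_t
#'   vectors); names are the cohort labels.
#' @param reference name of the reference cohort (default: the first).
#' @param n_iterations resampling iterations per test.
#' @param seed RNG seed for the tests.
#' @param bin_width histogram bin width (min).
#' @return list with \code{cohorts} (list of [CohortResult-class]),
#'   \code{comparisons} (data.frame: label, n, mean, sem, diff vs reference,
#'   p, stars, delta_t_ratio, percent_rate_reduction).
#' @export
compareCohorts <- function(events_list, reference = names(events_list)[1],
                           n_iterations = 1e6, seed = NULL, bin_width = 2) {
  stopifnot(!is.null(names(events_list)), reference %in% names(events_list))
  cohorts <- lapply(names(events_list), function(nm)
    summarizeCohort(events_list[[nm]], nm, bin_width))
  names(cohorts) <- names(events_list)
  ref_ev <- events_list[[reference]]
  others <- setdiff(names(events_list), reference)
  rows <- lapply(others, function(nm) {
    tst <- resamplingTest(events_list[[nm]], ref_ev,
                          n_iterations = n_iterations, seed = seed)
    fc <- foldChange(cohorts[[reference]], cohorts[[nm]])
    data.frame(label = nm, n = cohorts[[nm]]@n,
               mean_delta_t = cohorts[[nm]]@mean_delta_t,
               sem = cohorts[[nm]]@sem,
               diff_vs_reference = tst@observed_diff,
               p_value = tst@p_value, stars = starSignificance(tst@p_value),
               delta_t_ratio = fc$delta_t_ratio,
               percent_rate_reduction = fc$percent_rate_reduction)
  })
  list(cohorts = cohorts, reference = reference,
       comparisons = do.call(rbind, rows))
}
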