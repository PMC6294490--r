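# Generics and accessors. Slot access from user code should go through these.

#' Mid-rise time of a fitted intensity step
#'
#' @param x a [SigmoidFit-class].
#' @return the mid-rise time t_mid (min).
#' @export
setGeneric("tMid", function(x) standardGeneric("tMid"))

#' @rdname tMid
setMethod("tMid", "SigmoidFit", function(x) x@t_mid)

#' Plateau fold-increase of a fitted intensity step
#'
#' (B + A)/B; equals 2 for a clean operator-array duplication.
#'
#' @param x a [SigmoidFit-class].
#' @return the fitted late/early plateau ratio.
#' @export
setGeneric("plateauFold", function(x) standardGeneric("plateauFold"))

#' @rdname plateauFold
setMethod("plateauFold", "SigmoidFit", function(x) (x@B + x@A) / x@B)

#' p-value of a resampling test
#'
#' @param x a [ResamplingTestResult-class].
#' @return the achieved significance level, in (0, 1].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
setMethod("pValue", "ResamplingTestResult", function(x) x@p_value)

#' Cohort accessors
#'
#' @param x a [CohortResult-class].
#' @return number of cells, mean replication delay (min), or its SEM (min).
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
setMethod("nCells", "CohortResult", function(x) x@n)

#' @rdname nCells
#' @export
setGeneric("meanDeltaT", function(x) standardGeneric("meanDeltaT"))

#' @rdname nCells
setMethod("meanDeltaT", "CohortResult", function(x) x@mean_delta_t)

#' @rdname nCells
#' @export
setGeneric("semDeltaT", function(x) standardGeneric("semDeltaT"))

#' @rdname nCells
setMethod("semDeltaT", "CohortResult", function(x) x@sem)

#' Folded fraction predicted by a two-state melting fit
#'
#' Evaluates theta(T) = 1/(1 + exp(-(dH/R)(1/T_K - 1/Tm_K))) at the given
#' temperatures; theta(Tm) = 0.5 exactly.
#'
#' @param x a [MeltingFit-class].
#' @param temps temperatures (deg C).
#' @return folded fractions in (0, 1).
#' @export
setGeneric("foldedFraction", function(x, temps) standardGeneric("foldedFraction"))

#' @rdname foldedFraction
setMethod("foldedFraction", "MeltingFit", function(x, temps) {
  twoStateTheta(temps, x@Tm, x@dH_vH)
})

#' Trace accessors
#'
#' @param x a [CellTrace-class].
#' @param channel \code{"green"} or \code{"red"}.
#' @return acquisition times (min) or the intensity vector of one channel.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname traceTimes
setMethod("traceTimes", "CellTrace", function(x) x@times)

#' @rdname traceTimes
#' @export
setGeneric("traceIntensity", function(x, channel = c("green", "red"))
  standardGeneric("traceIntensity"))

#' @rdname traceTimes
setMethod("traceIntensity", "CellTrace", function(x, channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (channel == "green") x@intensity_green else x@intensity_red
})
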