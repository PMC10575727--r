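#' @include AllClasses.R AllGenerics.R electrophys.R
NULL

#' Fit an intracellular pH calibration curve
#'
#' Affine least-squares fit of pH on probe signal from nigericin/K+ clamp
#' segments in which intra- and extracellular pH are equalized at known
#' values (typically 6, 7 and 8). Over the 6-8 range three clamp points
#' cannot constrain a sigmoid, so the map is affine; clamp mean signals must
#' be strictly monotone in pH.
#'
#' @param clamps Either a data.frame with columns `pH` and `signal` (mean
#'   clamp signal), or a named list mapping pH value to a numeric vector of
#'   signal samples from that clamp segment.
#' @return A [CalibrationCurve-class].
#' @examples
#' fitCalibration(data.frame(pH = c(6, 7, 8), signal = c(0.2, 0.5, 0.8)))
#' @export
fitCalibration <- function(clamps) {
  if (is.list(clamps) && !is.data.frame(clamps)) {
    pts <- data.frame(pH = as.numeric(names(clamps)),
                      signal = vapply(clamps, mean, numeric(1)))
  } else {
    pts <- as.data.frame(clamps)[, c("pH", "signal")]
  }
  pts <- pts[order(pts$pH), ]
  if (nrow(pts) < 3L || anyDuplicated(pts$pH))
    stop("need at least 3 distinct clamp pH values", call. = FALSE)
  d <- diff(pts$signal)
  if (!(all(d > 0) || all(d < 0)))
    stop("clamp mean signals are not monotone in pH; calibration invalid",
         call. = FALSE)
  fit <- stats::lm(pH ~ signal, data = pts)
  new("CalibrationCurve", points = pts,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      residuals = as.numeric(stats::residuals(fit)),
      signalRange = range(pts$signal))
}

#' Convert a probe-signal trace to calibrated pH
#'
#' Elementwise affine mapping of a fluorescence trace through a fitted
#' calibration curve. Signals outside the calibrated range are still mapped
#' (linear extrapolation) but flagged.
#'
#' @param trace An [AssayTrace-class] of probe signal.
#' @param calibration A [CalibrationCurve-class].
#' @return An [AssayTrace-class] in pH units; the attribute
#'   `"extrapolated"` is a logical vector marking out-of-range samples.
#' @export
signalToPh <- function(trace, calibration) {
  stopifnot(is(trace, "AssayTrace"), is(calibration, "CalibrationCurve"))
  s <- traceValue(trace)
  ph <- calibration@intercept + calibration@slope * s
  out <- AssayTrace(traceTime(trace), ph, traceEvents(trace), unit = "pH")
  extr <- s < calibration@signalRange[1] | s > calibration@signalRange[2]
  if (any(extr))
    warning(sum(extr), " sample(s) outside the calibrated signal range ",
            "were extrapolated")
  attr(out, "extrapolated") <- extr
  out
}

#' Na+/H+ exchanger activity from a pH recovery trace
#'
#' Quantifies NHE-dependent alkalinization after Na+ re-addition following
#' an acidifying Na+-free (prepulse) period: the pH change from the
#' pre-re-addition baseline (mean over the 30 s before re-addition) to the
#' recovery plateau (mean over the final 10\% of the recovery window), and
#' the initial recovery rate (least-squares slope over the first 60 s of
#' recovery, requiring at least 5 samples).
#'
#' @param phTrace A calibrated pH [AssayTrace-class].
#' @param readditionTime Time (s) of Na+ re-addition, inside the trace.
#' @param window Length (s) of the recovery window after re-addition.
#' @param preWindow Baseline window length before re-addition (s,
#'   default 30).
#' @param rateWindow Window for the initial-rate slope (s, default 60).
#' @param plateauFraction Final fraction of the recovery window averaged
#'   for the plateau (default 0.1).
#' @return An [NheActivityResult-class].
#' @export
nheActivity <- function(phTrace, readditionTime, window, preWindow = 30,
                        rateWindow = 60, plateauFraction = 0.1) {
  stopifnot(is(phTrace, "AssayTrace"))
  tt <- traceTime(phTrace)
  if (readditionTime < min(tt) || readditionTime > max(tt))
    stop("re-addition time lies outside the trace", call. = FALSE)
  if (readditionTime + window > max(tt))
    stop("recovery window extends beyond the trace", call. = FALSE)
  base <- .windowMean(phTrace, readditionTime - preWindow, readditionTime)
  plateau <- .windowMean(phTrace,
                         readditionTime + window * (1 - plateauFraction),
                         readditionTime + window)
  sel <- tt >= readditionTime & tt <= readditionTime + min(rateWindow, window)
  if (sum(sel) < 5L)
    stop("recovery window too short: fewer than 5 samples for the ",
         "initial rate", call. = FALSE)
  fit <- stats::lm(traceValue(phTrace)[sel] ~ tt[sel])
  new("NheActivityResult", deltaPh = plateau - base,
      rate = unname(stats::coef(fit)[2]), nRate = sum(sel),
      flags = character())
}

#' Inhibitor-corrected NHE-dependent pH change
#'
#' Difference between the pH recovery of a test condition and that of a
#' paired NHE-inhibitor condition (e.g. S3226 pretreatment); the
#' inhibitor-resistant component is subtracted out. Negative differences
#' are floored at 0 and flagged.
#'
#' @param test,inhibitor [NheActivityResult-class] objects from comparable
#'   protocols.
#' @return The corrected delta pH (pH units); attribute
#'   `flag = "negative_difference"` when the raw difference was negative.
#' @examples
#' a <- new("NheActivityResult", deltaPh = 0.45, rate = 0.01,
#'          nRate = 10L, flags = character())
#' b <- new("NheActivityResult", deltaPh = 0.05, rate = 0.001,
#'          nRate = 10L, flags = character())
#' inhibitorCorrected(a, b)  # 0.40
#' @export
inhibitorCorrected <- function(test, inhibitor) {
  stopifnot(is(test, "NheActivityResult"), is(inhibitor, "NheActivityResult"))
  d <- test@deltaPh - inhibitor@deltaPh
  if (d < 0) {
    out <- 0
    attr(out, "flag") <- "negative_difference"
    return(out)
  }
  d
}
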