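#' @include AllClasses.R AllGenerics.R
NULL

.windowMean <- function(trace, from, to) {
  sel <- traceTime(trace) >= from & traceTime(trace) <= to
  if (!any(sel)) stop("no samples in window [", from, ", ", to, "] s",
                      call. = FALSE)
  mean(traceValue(trace)[sel])
}

#' Agonist-evoked change in short-circuit current
#'
#' Baseline-subtracted response to an annotated agonist addition. The
#' baseline is the mean current over a window preceding the event; the
#' response is either the maximum within the response window (`"peak"`,
#' suited to transient Ca2+-mediated carbachol responses) or the mean over
#' the final third of the response window (`"plateau"`, suited to sustained
#' cAMP-mediated forskolin responses).
#'
#' @param trace An [AssayTrace-class] with the event annotated.
#' @param event Agent label to locate in the trace events (first match).
#' @param mode `"plateau"` (default) or `"peak"`.
#' @param baselineWindow Length-2 offsets (s) relative to the event time;
#'   must end at or before the event.
#' @param responseWindow Length-2 offsets (s) relative to the event time.
#' @return Delta Isc in trace units (typically uA/cm2).
#' @examples
#' tr <- AssayTrace(0:100, c(rep(5, 50), rep(25, 51)),
#'                  data.frame(time = 49, agent = "forskolin"))
#' deltaIsc(tr, "forskolin", "plateau", c(-30, 0), c(0, 50))
#' @export
deltaIsc <- function(trace, event, mode = c("plateau", "peak"),
                     baselineWindow = c(-30, 0),
                     responseWindow = c(0, 120)) {
  stopifnot(is(trace, "AssayTrace"))
  mode <- match.arg(mode)
  ev <- traceEvents(trace)
  hit <- which(ev$agent == event)
  if (length(hit) == 0L)
    stop("event '", event, "' not found in trace annotations", call. = FALSE)
  t0 <- ev$time[hit[1L]]
  if (baselineWindow[2] > 0)
    stop("baseline window must precede the event", call. = FALSE)
  tt <- traceTime(trace)
  if (t0 + baselineWindow[1] < min(tt) || t0 + responseWindow[2] > max(tt))
    stop("analysis windows extend beyond the trace", call. = FALSE)
  base <- .windowMean(trace, t0 + baselineWindow[1], t0 + baselineWindow[2])
  if (mode == "peak") {
    sel <- tt >= t0 + responseWindow[1] & tt <= t0 + responseWindow[2]
    resp <- max(traceValue(trace)[sel])
  } else {
    w <- responseWindow[2] - responseWindow[1]
    resp <- .windowMean(trace, t0 + responseWindow[2] - w / 3,
                        t0 + responseWindow[2])
  }
  resp - base
}

#' Inhibitor-sensitive fraction of a stimulated current
#'
#' Percentage of the agonist-stimulated current blocked by an inhibitor:
#' `100 * (deltaControl - deltaInhibited) / deltaControl`. Used for, e.g.,
#' the CaCC-inhibitor-sensitive fraction of carbachol-stimulated current or
#' the phlorizin-sensitive fraction of glucose-stimulated current.
#'
#' @param deltaControl Delta Isc without inhibitor (non-zero).
#' @param deltaInhibited Delta Isc with inhibitor.
#' @return Percent blocked; carries the attribute `flag = "exceeds_100"`
#'   when the value is above 100 (inhibited response below zero).
#' @examples
#' sensitiveFraction(100, 20)  # 80
#' @export
sensitiveFraction <- function(deltaControl, deltaInhibited) {
  if (deltaControl == 0)
    stop("control response is zero; fraction undefined", call. = FALSE)
  out <- 100 * (deltaControl - deltaInhibited) / deltaControl
  if (out > 100) attr(out, "flag") <- "exceeds_100"
  out
}

#' Percent change relative to a reference
#'
#' `100 * (reference - test) / reference`: positive values are reductions
#' (e.g. the ~60\% loss of phlorizin-sensitive SGLT1 current in MVID
#' monolayers relative to controls), negative values increases.
#'
#' @param reference Reference value (non-zero).
#' @param test Test value.
#' @return Percent change.
#' @examples
#' percentChange(10, 4)  # 60
#' @export
percentChange <- function(reference, test) {
  if (reference == 0) stop("reference is zero; percent change undefined",
                           call. = FALSE)
  100 * (reference - test) / reference
}

.pl4 <- function(d, floor, ceiling, logIC50, slope) {
  floor + (ceiling - floor) / (1 + 10^(slope * (logIC50 - log10(d))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit of percent inhibition against dose in log10 dose:
#' `y = floor + (ceiling - floor) / (1 + 10^(slope * (log10(IC50) -
#' log10(dose))))`. By default the floor and ceiling are constrained to the
#' percent-inhibition scale \[0, 100\]; the ceiling is the maximal
#' inhibition.
#'
#' @param doses Positive doses (at least 4 distinct values).
#' @param response Percent inhibition at each dose.
#' @param lowerBounds,upperBounds Length-4 bounds on (floor, ceiling,
#'   log10 IC50, slope).
#' @return A [DoseResponseFit-class]; when the optimizer fails the
#'   `converged` slot is FALSE and parameters are `NA`.
#' @examples
#' d <- c(1, 3, 10, 30, 100, 300)
#' y <- 80 / (1 + 30 / d)
#' fitDoseResponse(d, y)
#' @export
fitDoseResponse <- function(doses, response,
                            lowerBounds = c(0, 0, -6, 0.1),
                            upperBounds = c(100, 100, 6, 10)) {
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (length(doses) != length(response))
    stop("doses and response lengths differ", call. = FALSE)
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses for a 4PL fit", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("degenerate (constant) response; nothing to fit", call. = FALSE)
  half <- (min(response) + max(response)) / 2
  start <- c(floor = max(min(response), lowerBounds[1]),
             ceiling = min(max(response), upperBounds[2]),
             logIC50 = log10(doses[which.min(abs(response - half))]),
             slope = 1)
  start <- pmin(pmax(start, lowerBounds + 1e-6), upperBounds - 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ .pl4(doses, floor, ceiling, logIC50, slope),
      start = as.list(start),
      lower = lowerBounds, upper = upperBounds,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("DoseResponseFit", floor = NA_real_, ceiling = NA_real_,
               ic50 = NA_real_, slope = NA_real_, doses = doses,
               response = response, residuals = rep(NA_real_, length(doses)),
               converged = FALSE))
  }
  cf <- stats::coef(fit)
  new("DoseResponseFit", floor = unname(cf["floor"]),
      ceiling = unname(cf["ceiling"]),
      ic50 = 10^unname(cf["logIC50"]), slope = unname(cf["slope"]),
      doses = doses, response = response,
      residuals = as.numeric(stats::residuals(fit)), converged = TRUE)
}
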