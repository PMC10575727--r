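#' @include AllClasses.R AllGenerics.R electrophys.R
NULL

#' Configuration for synthetic short-circuit-current traces
#'
#' Describes a simulated Ussing-chamber recording: a constant baseline plus
#' shaped responses to scheduled agent additions, optional dose-dependent
#' inhibition from a true 4PL curve, and additive Gaussian noise.
#'
#' @param duration Trace length (s).
#' @param dt Sampling interval (s).
#' @param baseline Baseline current (uA/cm2).
#' @param events data.frame with columns `time`, `agent`, `amplitude`,
#'   `shape` (`"sustained"` or `"peak"`) and optional `tau` (s) and
#'   `concentration`.
#' @param doses Strictly positive, strictly increasing dose vector for
#'   inhibition runs (optional).
#' @param pl4 True 4PL parameters for inhibition runs: list with `floor`,
#'   `ceiling` (percent inhibition), `ic50` (> 0) and `slope`.
#' @param stimAmplitude Uninhibited stimulated response amplitude
#'   (uA/cm2) for inhibition runs.
#' @param noiseSd Gaussian noise sd (uA/cm2); >= 0.
#' @param seed Integer seed.
#' @return Config list of class `"syntheticAssayConfig"`.
#' @export
syntheticAssayConfig <- function(duration = 600, dt = 1, baseline = 5,
                                 events = NULL, doses = NULL, pl4 = NULL,
                                 stimAmplitude = 50, noiseSd = 0,
                                 seed = 1) {
  if (noiseSd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (!is.null(doses)) {
    if (any(doses <= 0) || any(diff(doses) <= 0))
      stop("doses must be strictly positive and increasing", call. = FALSE)
    if (is.null(pl4)) stop("inhibition runs need pl4 truth", call. = FALSE)
  }
  if (!is.null(pl4)) {
    if (pl4$ic50 <= 0) stop("IC50 must be > 0", call. = FALSE)
    if (pl4$floor > pl4$ceiling)
      stop("floor must be <= ceiling", call. = FALSE)
  }
  if (!is.null(events)) {
    if (any(events$time < 0) || any(events$time > duration))
      stop("event times must lie within the trace duration", call. = FALSE)
    dup <- duplicated(events$time) | duplicated(events$time, fromLast = TRUE)
    if (any(dup) && length(unique(events$shape[dup])) > 1L)
      stop("overlapping events with incompatible shapes", call. = FALSE)
  }
  structure(list(duration = duration, dt = dt, baseline = baseline,
                 events = events, doses = doses, pl4 = pl4,
                 stimAmplitude = stimAmplitude, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "syntheticAssayConfig")
}

.eventResponse <- function(tt, t0, amplitude, shape, tau) {
  y <- numeric(length(tt))
  after <- tt >= t0
  dtb <- tt[after] - t0
  if (shape == "sustained") {
    tau <- if (is.na(tau)) 15 else tau
    y[after] <- amplitude * (1 - exp(-dtb / tau))
  } else if (shape == "peak") {
    tau <- if (is.na(tau)) 30 else tau
    y[after] <- amplitude * (dtb / tau) * exp(1 - dtb / tau)
  } else stop("unknown event shape: ", shape, call. = FALSE)
  y
}

#' Generate a synthetic short-circuit-current trace
#'
#' Baseline plus one shaped response per scheduled event (`"sustained"`
#' saturating rise for cAMP-type secretagogues, `"peak"` alpha-function
#' transient for Ca2+-type), plus Gaussian noise. The truth records each
#' event's planted amplitude.
#'
#' @param config A [syntheticAssayConfig()] with an `events` table.
#' @return List with `trace` ([AssayTrace-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
genIscTrace <- function(config) {
  stopifnot(inherits(config, "syntheticAssayConfig"))
  withr::with_seed(config$seed, {
    tt <- seq(0, config$duration, by = config$dt)
    y <- rep(config$baseline, length(tt))
    ev <- config$events
    if (!is.null(ev) && nrow(ev)) {
      if (is.null(ev$tau)) ev$tau <- NA_real_
      for (k in seq_len(nrow(ev)))
        y <- y + .eventResponse(tt, ev$time[k], ev$amplitude[k],
                                ev$shape[k], ev$tau[k])
      ann <- data.frame(time = ev$time, agent = ev$agent,
                        concentration = ev$concentration %||%
                          rep(NA_real_, nrow(ev)))
    } else {
      ann <- data.frame(time = numeric(), agent = character(),
                        concentration = numeric())
    }
    if (config$noiseSd > 0)
      y <- y + stats::rnorm(length(y), 0, config$noiseSd)
    list(trace = AssayTrace(tt, y, ann),
         truth = SyntheticTruth(
           list(baseline = config$baseline,
                amplitudes = if (!is.null(ev)) ev$amplitude else numeric()),
           config$seed, "isc"))
  })
}

#' Default crofelemer dose-inhibition configuration
#'
#' The generator's default crofelemer parameter set reproduces the study
#' conditions: combined forskolin + carbachol stimulation of 50 uA/cm2,
#' six crofelemer doses (1-300 uM), and a true 4PL inhibition curve with
#' floor 0, maximal inhibition 80 percent, IC50 30 uM and slope 1. Trace
#' noise sd is 5 percent of the stimulated amplitude.
#'
#' @param seed Integer seed.
#' @param noiseSd Noise sd (default 2.5 uA/cm2 = 5 percent of the
#'   stimulated response).
#' @return A [syntheticAssayConfig()].
#' @export
syntheticCrofelemerConfig <- function(seed = 1, noiseSd = 2.5) {
  syntheticAssayConfig(duration = 360, dt = 1, baseline = 5,
                       doses = c(1, 3, 10, 30, 100, 300),
                       pl4 = list(floor = 0, ceiling = 80, ic50 = 30,
                                  slope = 1),
                       stimAmplitude = 50, noiseSd = noiseSd, seed = seed)
}

#' Generate a dose-inhibition run
#'
#' One trace per condition — an uninhibited control plus one trace per dose
#' — in which a single combined secretagogue event (sustained shape, time
#' 120 s) is scaled down by the true 4PL percent inhibition at that dose.
#' The truth records the 4PL parameters and the per-dose true inhibition.
#'
#' @param config A [syntheticAssayConfig()] with `doses` and `pl4` set
#'   (e.g. [syntheticCrofelemerConfig()]).
#' @return List with `control` (trace), `traces` (one per dose), `doses`,
#'   and `truth`.
#' @export
genDoseInhibitionRun <- function(config) {
  stopifnot(inherits(config, "syntheticAssayConfig"))
  if (is.null(config$doses) || is.null(config$pl4))
    stop("config must carry doses and pl4 truth", call. = FALSE)
  p <- config$pl4
  inh <- .pl4(config$doses, p$floor, p$ceiling, log10(p$ic50), p$slope)
  mk <- function(amp, subSeed, conc) {
    cfg <- syntheticAssayConfig(
      duration = config$duration, dt = config$dt,
      baseline = config$baseline,
      events = data.frame(time = 120, agent = "fsk+cch", amplitude = amp,
                          shape = "sustained", tau = 15,
                          concentration = conc),
      noiseSd = config$noiseSd, seed = subSeed)
    genIscTrace(cfg)$trace
  }
  seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max %/% 2L, length(config$doses) + 1L))
  control <- mk(config$stimAmplitude, seeds[1], 0)
  traces <- lapply(seq_along(config$doses), function(k) {
    mk(config$stimAmplitude * (1 - inh[k] / 100), seeds[k + 1],
       config$doses[k])
  })
  list(control = control, traces = traces, doses = config$doses,
       truth = SyntheticTruth(list(pl4 = p, inhibition = inh,
                                   stimAmplitude = config$stimAmplitude),
                              config$seed, "dose_inhibition"))
}

#' Measure a dose-response from simulated or recorded traces
#'
#' Computes the agonist response of the control and of each dose condition
#' with [deltaIsc()] and expresses each dose as the percent of the control
#' response blocked ([sensitiveFraction()]).
#'
#' @param control Control (uninhibited) [AssayTrace-class].
#' @param traces List of per-dose traces.
#' @param doses Dose vector aligned with `traces`.
#' @param event Agent label of the stimulation event.
#' @param mode Response mode passed to [deltaIsc()].
#' @param baselineWindow,responseWindow Windows passed to [deltaIsc()].
#' @return data.frame with `dose` and `inhibition` (percent).
#' @export
measureDoseInhibition <- function(control, traces, doses,
                                  event = "fsk+cch", mode = "plateau",
                                  baselineWindow = c(-60, 0),
                                  responseWindow = c(0, 180)) {
  d0 <- deltaIsc(control, event, mode, baselineWindow, responseWindow)
  inh <- vapply(traces, function(tr) {
    as.numeric(sensitiveFraction(
      d0, deltaIsc(tr, event, mode, baselineWindow, responseWindow)))
  }, numeric(1))
  data.frame(dose = doses, inhibition = inh)
}

#' Default glucose/phlorizin (SGLT1) protocol configuration
#'
#' Simulated glucose-stimulated, phlorizin-inhibitable current in
#' differentiated monolayers. The control glucose-stimulated amplitude is
#' 20 uA/cm2; the MVID amplitude is reduced by 60 percent (8 uA/cm2),
#' the study's reported SGLT1 deficit. Phlorizin fully blocks the
#' glucose-stimulated component. Between-monolayer variability is a
#' multiplicative Gaussian with 10 percent CV.
#'
#' @param condition `"control"` or `"mvid"`.
#' @param nMonolayers Monolayers per group (default 4).
#' @param monolayerCv Between-monolayer coefficient of variation
#'   (default 0.1).
#' @param noiseSd Trace noise sd (default 0.5 uA/cm2).
#' @param seed Integer seed.
#' @return Config list of class `"syntheticSglt1Config"`.
#' @export
syntheticSglt1Config <- function(condition = c("control", "mvid"),
                                 nMonolayers = 4, monolayerCv = 0.1,
                                 noiseSd = 0.5, seed = 1) {
  condition <- match.arg(condition)
  amp <- if (condition == "control") 20 else 20 * (1 - 0.60)
  structure(list(condition = condition, glucoseAmplitude = amp,
                 nMonolayers = nMonolayers, monolayerCv = monolayerCv,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "syntheticSglt1Config")
}

#' Generate glucose/phlorizin traces for a group of monolayers
#'
#' Each monolayer trace carries a sustained glucose-stimulated rise
#' (t = 180 s) and a sustained phlorizin block (t = 540 s) of equal and
#' opposite amplitude, scaled by the monolayer's multiplicative
#' variability. The truth records per-monolayer planted amplitudes.
#'
#' @param config A [syntheticSglt1Config()].
#' @return List with `traces` (list of [AssayTrace-class]) and `truth`.
#' @export
genSglt1Traces <- function(config) {
  stopifnot(inherits(config, "syntheticSglt1Config"))
  withr::with_seed(config$seed, {
    mult <- pmax(0.2, stats::rnorm(config$nMonolayers, 1,
                                   config$monolayerCv))
    subSeeds <- sample.int(.Machine$integer.max %/% 2L,
                           config$nMonolayers)
    amps <- config$glucoseAmplitude * mult
    traces <- lapply(seq_len(config$nMonolayers), function(i) {
      cfg <- syntheticAssayConfig(
        duration = 900, dt = 1, baseline = 5,
        events = data.frame(
          time = c(180, 540), agent = c("glucose", "phlorizin"),
          amplitude = c(amps[i], -amps[i]),
          shape = "sustained", tau = 15,
          concentration = c(20000, 200)),
        noiseSd = config$noiseSd, seed = subSeeds[i])
      genIscTrace(cfg)$trace
    })
    list(traces = traces,
         truth = SyntheticTruth(list(condition = config$condition,
                                     glucoseAmplitudes = amps),
                                config$seed, "sglt1"))
  })
}

#' Configuration for synthetic pH-probe traces
#'
#' A Na+-free acidified plateau, an exponential NHE-driven recovery of
#' stated magnitude and rate after Na+ re-addition, and three nigericin
#' calibration clamp segments (default pH 6, 7, 8), all expressed through a
#' stated affine signal-vs-pH map plus Gaussian noise.
#'
#' @param clampPh Distinct clamp pH values (default 6, 7, 8).
#' @param signalSlope,signalIntercept Affine map `signal = slope * pH +
#'   intercept` (defaults 0.3 and -1.5).
#' @param startPh Acidified starting pH after the prepulse (default 6.6).
#' @param deltaPh True recovery magnitude in pH units (>= 0; default 0.5).
#' @param rate Exponential recovery rate constant (1/s; default 0.02).
#' @param inhibitor If TRUE the recovery is scaled by `inhibitorScale`
#'   (NHE-inhibitor pretreatment condition).
#' @param inhibitorScale Residual recovery fraction under inhibitor
#'   (default 0.1).
#' @param noiseSd Signal noise sd (default 0.005).
#' @param dt Sampling interval (s; default 2).
#' @param seed Integer seed.
#' @return Config list of class `"syntheticPhConfig"`.
#' @export
syntheticPhConfig <- function(clampPh = c(6, 7, 8), signalSlope = 0.3,
                              signalIntercept = -1.5, startPh = 6.6,
                              deltaPh = 0.5, rate = 0.02,
                              inhibitor = FALSE, inhibitorScale = 0.1,
                              noiseSd = 0.005, dt = 2, seed = 1) {
  if (anyDuplicated(clampPh) || length(clampPh) < 3L)
    stop("clamp pH values must be >= 3 distinct values", call. = FALSE)
  if (deltaPh < 0) stop("recovery magnitude must be >= 0", call. = FALSE)
  structure(list(clampPh = sort(clampPh), signalSlope = signalSlope,
                 signalIntercept = signalIntercept, startPh = startPh,
                 deltaPh = deltaPh, rate = rate, inhibitor = inhibitor,
                 inhibitorScale = inhibitorScale, noiseSd = noiseSd,
                 dt = dt, seed = as.integer(seed)),
            class = "syntheticPhConfig")
}

#' Generate a synthetic SNARF-like pH trace
#'
#' Timeline: Na+-free plateau at the acidified start pH (0-120 s), Na+
#' re-addition at 120 s followed by an exponential recovery of the
#' configured magnitude and rate (to 600 s), then one 120 s calibration
#' clamp segment per clamp pH. The measured value is the affine-mapped
#' signal plus noise. Events annotate the re-addition
#' (`"Na_readdition"`) and each clamp (`"clamp_pH<value>"`).
#'
#' @param config A [syntheticPhConfig()].
#' @return List with `trace` ([AssayTrace-class], signal units), `truth`
#'   (effective delta pH after any inhibitor scaling, rate, map
#'   coefficients, re-addition time and recovery window length).
#' @export
genPhTrace <- function(config) {
  stopifnot(inherits(config, "syntheticPhConfig"))
  withr::with_seed(config$seed, {
    dEff <- config$deltaPh *
      (if (config$inhibitor) config$inhibitorScale else 1)
    tRe <- 120
    tEndRec <- 600
    clampLen <- 120
    gap <- 20
    nClamp <- length(config$clampPh)
    clampStarts <- tEndRec + gap + (seq_len(nClamp) - 1) * (clampLen + gap)
    duration <- clampStarts[nClamp] + clampLen
    tt <- seq(0, duration, by = config$dt)
    ph <- rep(config$startPh, length(tt))
    rec <- tt >= tRe & tt < tEndRec + gap
    ph[rec] <- config$startPh +
      dEff * (1 - exp(-config$rate * (tt[rec] - tRe)))
    for (k in seq_len(nClamp)) {
      seg <- tt >= clampStarts[k] & tt < clampStarts[k] + clampLen +
        (if (k == nClamp) config$dt else gap)
      ph[seg] <- config$clampPh[k]
    }
    sig <- config$signalSlope * ph + config$signalIntercept
    if (config$noiseSd > 0)
      sig <- sig + stats::rnorm(length(sig), 0, config$noiseSd)
    ev <- data.frame(
      time = c(tRe, clampStarts),
      agent = c("Na_readdition",
                paste0("clamp_pH", config$clampPh)),
      concentration = NA_real_)
    list(trace = AssayTrace(tt, sig, ev, unit = "au"),
         truth = SyntheticTruth(
           list(deltaPh = dEff, rate = config$rate,
                startPh = config$startPh,
                signalSlope = config$signalSlope,
                signalIntercept = config$signalIntercept,
                clampPh = config$clampPh,
                readditionTime = tRe, recoveryWindow = tEndRec - tRe),
           config$seed, "ph"))
  })
}

#' Extract calibration clamp segments from an annotated trace
#'
#' Collects, for every event labelled `clamp_pH<value>`, the signal samples
#' from a stabilized window inside that clamp segment, in the named-list
#' form [fitCalibration()] accepts.
#'
#' @param trace An [AssayTrace-class] with clamp events.
#' @param clampDuration Segment length read per clamp (s; default 100).
#' @param skip Settling time skipped at the start of each clamp (s;
#'   default 10).
#' @return Named list: clamp pH value -> numeric signal vector.
#' @export
clampSegments <- function(trace, clampDuration = 100, skip = 10) {
  ev <- traceEvents(trace)
  sel <- grepl("^clamp_pH", ev$agent)
  if (sum(sel) < 3L)
    stop("trace must annotate at least 3 clamp_pH events", call. = FALSE)
  tt <- traceTime(trace)
  out <- lapply(which(sel), function(k) {
    w <- tt >= ev$time[k] + skip & tt <= ev$time[k] + skip + clampDuration
    traceValue(trace)[w]
  })
  names(out) <- sub("^clamp_pH", "", ev$agent[sel])
  out
}
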