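#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("hclustOrNULL", c("NULL"))
setOldClass("hclust")
setClassUnion("hclustOrNULL", c("hclust", "NULL"))

#' Multichannel fluorescence image
#'
#' Container for a background-corrected multiplex immunofluorescence field:
#' one 2D non-negative intensity grid per named channel, an optional binary
#' tissue mask of the same dimensions, and an optional pixel size in
#' micrometres per pixel.
#'
#' @slot channels Named list of numeric matrices, all with identical
#'   dimensions; intensities are arbitrary fluorescence units, >= 0.
#' @slot mask Logical matrix of the same dimensions restricting analysis to
#'   tissue, or `NULL` for whole-field analysis.
#' @slot pixelSize Micrometres per pixel (`NA_real_` if unknown).
#'
#' @seealso [MultichannelImage()], [findMaxima()], [channelCrossCorrelation()]
#' @export
setClass("MultichannelImage",
  representation(channels = "list", mask = "matrixOrNULL",
                 pixelSize = "numeric"),
  prototype(channels = list(), mask = NULL, pixelSize = NA_real_))

setValidity("MultichannelImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(names(ch) == "") || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  dims <- lapply(ch, dim)
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a matrix")
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all channels must share dimensions")
  if (any(vapply(ch, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    return("channel intensities must be non-negative")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dims[[1]]))
      return("mask must share channel dimensions")
    if (!is.logical(object@mask))
      return("mask must be logical")
  }
  if (length(object@pixelSize) != 1L)
    return("pixelSize must be length 1")
  TRUE
})

#' Construct a MultichannelImage
#'
#' @param channels Named list of same-size non-negative intensity matrices.
#' @param mask Optional logical tissue mask matrix.
#' @param pixelSize Optional micrometres per pixel.
#' @return A [MultichannelImage-class] object.
#' @examples
#' img <- MultichannelImage(list(DAPI = matrix(0, 8, 8)))
#' channelNames(img)
#' @export
MultichannelImage <- function(channels, mask = NULL, pixelSize = NA_real_) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("MultichannelImage", channels = channels, mask = mask,
      pixelSize = as.numeric(pixelSize))
}

#' Local-maxima counting result
#'
#' Holds the coordinates of the regional maxima of one channel that survive a
#' prominence criterion, as produced by [findMaxima()].
#'
#' @slot channel Channel name the maxima were detected in.
#' @slot prominence Prominence used, in intensity units.
#' @slot coords Integer matrix with columns `row`, `col`, one row per
#'   accepted maximum (plateaus are reduced to the pixel nearest their
#'   centroid).
#' @export
setClass("MaximaResult",
  representation(channel = "character", prominence = "numeric",
                 coords = "matrix"))

setValidity("MaximaResult", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns")
  if (object@prominence <= 0) return("prominence must be positive")
  TRUE
})

#' Skeletonized marker signal
#'
#' Connected one-pixel-wide curve components obtained by thresholding,
#' binarizing and thinning a marker channel (e.g. CD10 brush-border signal),
#' with spur branches below a minimum length pruned.
#'
#' @slot components List of integer matrices (columns `row`, `col`), one per
#'   8-connected skeleton component; every component has at least 2 pixels.
#' @slot channel Source channel name.
#' @slot threshold Intensity threshold that produced the binary mask.
#' @slot minBranchLength Minimum branch length applied, in pixels.
#' @slot dim Dimensions of the source image.
#' @export
setClass("SkeletonSet",
  representation(components = "list", channel = "character",
                 threshold = "numeric", minBranchLength = "numeric",
                 dim = "integer"))

setValidity("SkeletonSet", function(object) {
  if (length(object@components) &&
      any(vapply(object@components, nrow, integer(1)) < 2L))
    return("every skeleton component must have >= 2 pixels")
  TRUE
})

#' Feret caliper summary over skeleton components
#'
#' Per-component maximum caliper (Feret) distances in pixels (and micrometres
#' when the pixel size is known), with distribution summaries. Used as the
#' brush-border continuity metric: longer calipers mean more continuous
#' brush-border ribbons.
#'
#' @slot perComponent data.frame with columns `component`, `caliper_px` and,
#'   when pixel size is known, `caliper_um`.
#' @slot pixelSize Micrometres per pixel or `NA`.
#' @export
setClass("FeretSummary",
  representation(perComponent = "data.frame", pixelSize = "numeric"))

#' Pairwise channel correlation matrix
#'
#' Symmetric matrix of Pearson correlation coefficients between channel
#' intensity grids, optionally with a hierarchical clustering of channels on
#' the distance 1 - r.
#'
#' @slot r Square symmetric numeric matrix, unit diagonal, entries in
#'   \[-1, 1\] (or `NA` for constant channels).
#' @slot tree `hclust` tree over channels, or `NULL` before clustering.
#' @slot order Integer leaf order after clustering (empty before).
#' @export
setClass("ChannelCorrelationMatrix",
  representation(r = "matrix", tree = "hclustOrNULL", order = "integer"),
  prototype(tree = NULL, order = integer()))

setValidity("ChannelCorrelationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("matrix must be square")
  if (!isTRUE(all.equal(r, t(r), check.attributes = FALSE)))
    return("matrix must be symmetric")
  d <- diag(r)
  if (any(!is.na(d) & abs(d - 1) > 1e-8)) return("diagonal must be 1")
  if (any(!is.na(r) & (r < -1 - 1e-8 | r > 1 + 1e-8)))
    return("entries must lie in [-1, 1]")
  TRUE
})

#' Timestamped assay trace
#'
#' A scalar time series — short-circuit current (uA/cm^2) or pH-probe
#' fluorescence (arbitrary units) — with annotated intervention events
#' (agonist/inhibitor additions, buffer switches, calibration clamps).
#'
#' @slot time Numeric vector of seconds, strictly increasing.
#' @slot value Numeric vector, same length as `time`.
#' @slot events data.frame with columns `time`, `agent`, `concentration`.
#' @slot unit Unit of `value` (e.g. `"uA/cm2"`, `"au"`, `"pH"`).
#' @export
setClass("AssayTrace",
  representation(time = "numeric", value = "numeric", events = "data.frame",
                 unit = "character"))

setValidity("AssayTrace", function(object) {
  if (length(object@time) != length(object@value))
    return("time and value must have equal length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  ev <- object@events
  if (!all(c("time", "agent") %in% names(ev)))
    return("events must have columns time and agent")
  if (nrow(ev) && (any(ev$time < min(object@time)) ||
                   any(ev$time > max(object@time))))
    return("event times must lie within the trace time range")
  TRUE
})

#' Construct an AssayTrace
#'
#' @param time Seconds, strictly increasing.
#' @param value Measured values.
#' @param events data.frame of interventions (`time`, `agent`, optionally
#'   `concentration`).
#' @param unit Value unit.
#' @return An [AssayTrace-class] object.
#' @export
AssayTrace <- function(time, value,
                       events = data.frame(time = numeric(),
                                           agent = character(),
                                           concentration = numeric()),
                       unit = "uA/cm2") {
  if (is.null(events$concentration)) events$concentration <- NA_real_
  new("AssayTrace", time = as.numeric(time), value = as.numeric(value),
      events = events, unit = unit)
}

#' Four-parameter logistic dose-response fit
#'
#' Result of fitting percent inhibition against dose with a 4PL model
#' in log10 dose: floor, ceiling (maximal inhibition), IC50 and Hill slope.
#'
#' @slot floor,ceiling Percent-inhibition asymptotes (floor <= ceiling).
#' @slot ic50 Half-maximal inhibitory concentration (same unit as doses).
#' @slot slope Hill slope.
#' @slot doses,response The fitted data.
#' @slot residuals Per-dose residuals.
#' @slot converged Logical convergence flag; parameters are `NA` when FALSE.
#' @export
setClass("DoseResponseFit",
  representation(floor = "numeric", ceiling = "numeric", ic50 = "numeric",
                 slope = "numeric", doses = "numeric", response = "numeric",
                 residuals = "numeric", converged = "logical"))

setValidity("DoseResponseFit", function(object) {
  if (object@converged) {
    if (!is.na(object@ic50) && object@ic50 <= 0) return("IC50 must be > 0")
    if (!is.na(object@floor) && !is.na(object@ceiling) &&
        object@floor > object@ceiling + 1e-8)
      return("floor must be <= ceiling")
  }
  TRUE
})

#' Intracellular pH calibration curve
#'
#' Affine map from probe signal to pH fitted from nigericin/K+ clamp
#' segments (pH set to known values, typically 6, 7 and 8).
#'
#' @slot points data.frame of clamp points (`pH`, `signal` = mean segment
#'   signal).
#' @slot slope,intercept Coefficients of pH = intercept + slope * signal.
#' @slot residuals Fit residuals (pH units) at the clamp points.
#' @slot signalRange Valid (calibrated) signal range; values outside are
#'   extrapolated and flagged by [signalToPh()].
#' @export
setClass("CalibrationCurve",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", residuals = "numeric",
                 signalRange = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (nrow(object@points) < 3L) return("at least 3 clamp points required")
  TRUE
})

#' Na+/H+ exchanger activity result
#'
#' Quantifies NHE-dependent alkalinization after Na+ re-addition: the pH
#' change over the recovery window and the initial recovery rate.
#'
#' @slot deltaPh pH units gained over the recovery window.
#' @slot rate Initial recovery rate, pH units per second.
#' @slot nRate Number of samples the rate was computed from (>= 5).
#' @slot flags Character vector of quality flags (e.g. `"extrapolated"`).
#' @export
setClass("NheActivityResult",
  representation(deltaPh = "numeric", rate = "numeric", nRate = "integer",
                 flags = "character"))

#' Differential-expression contrast table
#'
#' Per-gene differential-expression results for one named contrast, as
#' produced by an upstream DE engine: log2 fold change, FDR-adjusted p value
#' and base mean expression.
#'
#' @slot contrast Contrast name (e.g. `"mvid_vs_healthy"`).
#' @slot data data.frame with columns `gene`, `log2fc`, `padj`, `basemean`;
#'   gene ids unique, padj in \[0, 1\], basemean >= 0.
#' @export
setClass("DeContrastTable",
  representation(contrast = "character", data = "data.frame"))

setValidity("DeContrastTable", function(object) {
  d <- object@data
  need <- c("gene", "log2fc", "padj", "basemean")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(d$gene)) return("gene ids must be unique")
  if (any(!is.na(d$padj) & (d$padj < 0 | d$padj > 1)))
    return("padj must lie in [0, 1]")
  if (any(d$basemean < 0, na.rm = TRUE)) return("basemean must be >= 0")
  TRUE
})

#' Construct a DeContrastTable
#'
#' @param contrast Contrast name.
#' @param data data.frame with `gene`, `log2fc`, `padj`, `basemean`.
#' @return A [DeContrastTable-class] object.
#' @export
DeContrastTable <- function(contrast, data) {
  new("DeContrastTable", contrast = contrast,
      data = as.data.frame(data, stringsAsFactors = FALSE))
}

#' Rescue gene set
#'
#' Genes significantly altered in the disease-vs-healthy baseline contrast
#' and significantly altered in the opposite direction by drug treatment,
#' with the per-gene statistics from both contrasts, a direction class and
#' any prioritization thresholds applied.
#'
#' @slot genes data.frame with columns `gene`, `baseline_log2fc`,
#'   `baseline_padj`, `treatment_log2fc`, `treatment_padj`, `basemean`,
#'   `direction` (`"down_up"` = down in disease / up with drug, or
#'   `"up_down"`).
#' @slot fdrCutoff FDR cutoff used by the filter.
#' @slot thresholds Named list of prioritization thresholds applied
#'   (empty before [prioritizeRescueGenes()]).
#' @export
setClass("RescueGeneSet",
  representation(genes = "data.frame", fdrCutoff = "numeric",
                 thresholds = "list"),
  prototype(thresholds = list()))

#' qPCR plate
#'
#' Long-format Cq measurements: one row per well, with sample, target gene,
#' role (target or housekeeping) and condition labels. Reactions are
#' typically run in triplicate.
#'
#' @slot wells data.frame with columns `sample`, `gene`, `cq`, `role`
#'   (`"target"` or `"housekeeping"`), `condition`.
#' @export
setClass("QpcrPlate", representation(wells = "data.frame"))

setValidity("QpcrPlate", function(object) {
  w <- object@wells
  need <- c("sample", "gene", "cq", "role")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns", paste(need, collapse = ", ")))
  if (any(w$cq <= 0, na.rm = TRUE)) return("Cq values must be positive")
  if (!all(w$role %in% c("target", "housekeeping")))
    return("role must be 'target' or 'housekeeping'")
  TRUE
})

#' Construct a QpcrPlate
#' @param wells Long-format data.frame (`sample`, `gene`, `cq`, `role`,
#'   optionally `condition`).
#' @return A [QpcrPlate-class] object.
#' @export
QpcrPlate <- function(wells) {
  if (is.null(wells$condition)) wells$condition <- NA_character_
  new("QpcrPlate", wells = as.data.frame(wells, stringsAsFactors = FALSE))
}

#' Planted ground truth for a synthetic dataset
#'
#' Every generator returns, alongside its dataset, the ground truth it
#' planted (spot centers, fragment lengths, event amplitudes, true 4PL
#' parameters, true delta-pH, rescue-gene identifiers, growth factors) plus
#' the seed, so downstream recovery can be tested.
#'
#' @slot truth Named list of planted quantities.
#' @slot seed Integer seed the dataset was generated from.
#' @slot modality Generator name.
#' @export
setClass("SyntheticTruth",
  representation(truth = "list", seed = "integer", modality = "character"))

SyntheticTruth <- function(truth, seed, modality) {
  new("SyntheticTruth", truth = truth, seed = as.integer(seed),
      modality = modality)
}

#' Set of enteroid tracks across timepoints
#'
#' Per-object trajectories through a swelling time series: centroid, pixel
#' area and equivalent circular diameter at each timepoint, plus condition
#' labels (agonist, inhibitor, dose).
#'
#' @slot tracks data.frame with columns `id`, `time`, `row`, `col`, `area`,
#'   `diameter`.
#' @slot condition Named list of condition labels.
#' @export
setClass("EnteroidTrackSet",
  representation(tracks = "data.frame", condition = "list"),
  prototype(condition = list()))

setValidity("EnteroidTrackSet", function(object) {
  tr <- object@tracks
  need <- c("id", "time", "area", "diameter")
  if (!all(need %in% names(tr)))
    return(paste("tracks must have columns", paste(need, collapse = ", ")))
  if (any(tr$area <= 0)) return("areas must be positive")
  TRUE
})

#' Swelling summary
#'
#' Per-track diameter ratios relative to t0 at each requested time, with
#' group distribution summaries.
#'
#' @slot ratios data.frame with columns `id`, `time`, `ratio`.
#' @slot summary data.frame with per-time `median` and interquartile range.
#' @export
setClass("SwellingSummary",
  representation(ratios = "data.frame", summary = "data.frame"))
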