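#' @include AllClasses.R
NULL

#' Accessors for enteroquant classes
#'
#' Small accessor generics: `channelNames` and `getChannel` read channels of
#' a [MultichannelImage-class]; `tissueMask` returns its mask; `nMaxima` and
#' `maximaCoords` read a [MaximaResult-class]; `skeletonComponents` the
#' components of a [SkeletonSet-class]; `feretTable` the per-component table
#' of a [FeretSummary-class]; `correlationMatrix` the Pearson matrix of a
#' [ChannelCorrelationMatrix-class]; `traceTime`, `traceValue` and
#' `traceEvents` the slots of an [AssayTrace-class]; `contrastData` the
#' per-gene table of a [DeContrastTable-class]; `rescueGenes` the gene table
#' of a [RescueGeneSet-class]; `truthOf` the planted list of a
#' [SyntheticTruth-class].
#'
#' @param x Object to access.
#' @param name Channel name (for `getChannel`).
#' @return The corresponding slot value (see each class's documentation).
#' @name accessors
#' @aliases channelNames getChannel tissueMask nMaxima maximaCoords
#'   skeletonComponents feretTable correlationMatrix traceTime traceValue
#'   traceEvents contrastData rescueGenes truthOf
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("nMaxima", function(x) standardGeneric("nMaxima"))
#' @rdname accessors
#' @export
setGeneric("maximaCoords", function(x) standardGeneric("maximaCoords"))
#' @rdname accessors
#' @export
setGeneric("skeletonComponents",
           function(x) standardGeneric("skeletonComponents"))
#' @rdname accessors
#' @export
setGeneric("feretTable", function(x) standardGeneric("feretTable"))
#' @rdname accessors
#' @export
setGeneric("correlationMatrix",
           function(x) standardGeneric("correlationMatrix"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceValue", function(x) standardGeneric("traceValue"))
#' @rdname accessors
#' @export
setGeneric("traceEvents", function(x) standardGeneric("traceEvents"))
#' @rdname accessors
#' @export
setGeneric("contrastData", function(x) standardGeneric("contrastData"))
#' @rdname accessors
#' @export
setGeneric("rescueGenes", function(x) standardGeneric("rescueGenes"))
#' @rdname accessors
#' @export
setGeneric("truthOf", function(x) standardGeneric("truthOf"))

#' @rdname accessors
setMethod("channelNames", "MultichannelImage",
          function(x) names(x@channels))
#' @rdname accessors
setMethod("getChannel", "MultichannelImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'", call. = FALSE)
  x@channels[[name]]
})
#' @rdname accessors
setMethod("tissueMask", "MultichannelImage", function(x) x@mask)
#' @rdname accessors
setMethod("nMaxima", "MaximaResult", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("maximaCoords", "MaximaResult", function(x) x@coords)
#' @rdname accessors
setMethod("skeletonComponents", "SkeletonSet", function(x) x@components)
#' @rdname accessors
setMethod("feretTable", "FeretSummary", function(x) x@perComponent)
#' @rdname accessors
setMethod("correlationMatrix", "ChannelCorrelationMatrix", function(x) x@r)
#' @rdname accessors
setMethod("traceTime", "AssayTrace", function(x) x@time)
#' @rdname accessors
setMethod("traceValue", "AssayTrace", function(x) x@value)
#' @rdname accessors
setMethod("traceEvents", "AssayTrace", function(x) x@events)
#' @rdname accessors
setMethod("contrastData", "DeContrastTable", function(x) x@data)
#' @rdname accessors
setMethod("rescueGenes", "RescueGeneSet", function(x) x@genes)
#' @rdname accessors
setMethod("truthOf", "SyntheticTruth", function(x) x@truth)

setMethod("show", "MultichannelImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("MultichannelImage:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  if (!is.null(object@mask))
    cat("  tissue mask:", sum(object@mask), "px in mask\n")
  if (!is.na(object@pixelSize))
    cat("  pixel size:", object@pixelSize, "um/px\n")
})

setMethod("show", "MaximaResult", function(object) {
  cat("MaximaResult:", nrow(object@coords), "maxima in channel '",
      object@channel, "' (prominence ", object@prominence, ")\n", sep = "")
})

setMethod("show", "SkeletonSet", function(object) {
  cat("SkeletonSet:", length(object@components),
      "component(s) from channel '", object@channel,
      "', threshold ", signif(object@threshold, 4),
      ", min branch ", object@minBranchLength, " px\n", sep = "")
})

setMethod("show", "FeretSummary", function(object) {
  p <- object@perComponent
  cat("FeretSummary over", nrow(p), "skeleton component(s)\n")
  if (nrow(p))
    cat("  caliper (px): mean", signif(mean(p$caliper_px), 4),
        "median", signif(stats::median(p$caliper_px), 4),
        "range [", signif(min(p$caliper_px), 4), ",",
        signif(max(p$caliper_px), 4), "]\n")
})

setMethod("show", "ChannelCorrelationMatrix", function(object) {
  cat("ChannelCorrelationMatrix over", nrow(object@r), "channels\n")
  print(round(object@r, 3))
  if (length(object@order))
    cat("  clustered leaf order:",
        paste(rownames(object@r)[object@order], collapse = ", "), "\n")
})

setMethod("show", "AssayTrace", function(object) {
  cat("AssayTrace:", length(object@time), "samples over",
      signif(diff(range(object@time)), 5), "s (", object@unit, "), ",
      nrow(object@events), "event(s)\n", sep = " ")
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cat("DoseResponseFit (4PL): IC50 =", signif(object@ic50, 4),
        " ceiling =", signif(object@ceiling, 4),
        "% floor =", signif(object@floor, 4),
        "% slope =", signif(object@slope, 3), "\n")
  } else {
    cat("DoseResponseFit: did not converge\n")
  }
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: pH =", signif(object@intercept, 4), "+",
      signif(object@slope, 4), "* signal;",
      nrow(object@points), "clamp points\n")
})

setMethod("show", "NheActivityResult", function(object) {
  cat("NheActivityResult: deltaPh =", signif(object@deltaPh, 4),
      "pH, initial rate =", signif(object@rate, 4), "pH/s")
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ", "),
                                "]", sep = "")
  cat("\n")
})

setMethod("show", "DeContrastTable", function(object) {
  cat("DeContrastTable '", object@contrast, "': ", nrow(object@data),
      " genes\n", sep = "")
})

setMethod("show", "RescueGeneSet", function(object) {
  cat("RescueGeneSet:", nrow(object@genes), "gene(s) at FDR <",
      object@fdrCutoff, "\n")
  if (length(object@thresholds))
    cat("  prioritized with:",
        paste(names(object@thresholds), unlist(object@thresholds),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (", object@modality, ", seed ", object@seed, "): ",
      paste(names(object@truth), collapse = ", "), "\n", sep = "")
})

setMethod("show", "EnteroidTrackSet", function(object) {
  cat("EnteroidTrackSet:", length(unique(object@tracks$id)), "track(s),",
      length(unique(object@tracks$time)), "timepoint(s)\n")
})
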