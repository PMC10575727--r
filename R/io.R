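#' @include AllClasses.R AllGenerics.R
NULL

#' Read and write multichannel images as TIFF with a channel sidecar
#'
#' Images are stored as multi-page 32-bit float TIFF (one page per channel,
#' intensities divided by a stored scale so values fit \[0, 1\]) with a
#' tab-delimited sidecar `<name>_channels.tsv` recording channel names, the
#' scale and the pixel size; a logical tissue mask, when present, is stored
#' as `<name>_mask.tif`. The round trip is lossless to 32-bit float
#' precision.
#'
#' @param image A [MultichannelImage-class].
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @param path Path to the `.tif` written by `writeMultichannelImage`.
#' @return `writeMultichannelImage` returns the TIFF path invisibly;
#'   `readMultichannelImage` returns a [MultichannelImage-class].
#' @name imageIO
NULL

#' @rdname imageIO
#' @export
writeMultichannelImage <- function(image, dir, name) {
  stopifnot(is(image, "MultichannelImage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(1, vapply(image@channels, max, numeric(1)))
  pages <- lapply(image@channels, function(m) m / scale)
  tifPath <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 32L)
  side <- data.frame(channel = names(image@channels),
                     page = seq_along(image@channels),
                     scale = scale, pixel_size = image@pixelSize)
  utils::write.table(side, file.path(dir, paste0(name, "_channels.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image@mask))
    tiff::writeTIFF(image@mask * 1,
                    file.path(dir, paste0(name, "_mask.tif")),
                    bits.per.sample = 8L)
  invisible(tifPath)
}

#' @rdname imageIO
#' @export
readMultichannelImage <- function(path) {
  base <- sub("\\.tif$", "", path)
  side <- utils::read.delim(paste0(base, "_channels.tsv"))
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(side$page, function(p) pages[[p]] * side$scale[1])
  names(channels) <- side$channel
  maskPath <- paste0(base, "_mask.tif")
  mask <- if (file.exists(maskPath)) tiff::readTIFF(maskPath) > 0.5 else NULL
  MultichannelImage(channels, mask = mask,
                    pixelSize = side$pixel_size[1])
}

#' Read and write assay traces as tab-delimited text
#'
#' A trace is stored as a two-column `time`/`value` table plus an events
#' sidecar `<base>_events.tsv` (`time`, `agent`, `concentration`).
#'
#' @param trace An [AssayTrace-class].
#' @param path Path of the trace `.tsv`.
#' @param unit Unit recorded in the returned trace (read side).
#' @return `writeAssayTrace` returns `path` invisibly; `readAssayTrace`
#'   returns an [AssayTrace-class].
#' @name traceIO
NULL

#' @rdname traceIO
#' @export
writeAssayTrace <- function(trace, path) {
  stopifnot(is(trace, "AssayTrace"))
  utils::write.table(data.frame(time = traceTime(trace),
                                value = traceValue(trace)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traceEvents(trace),
                     paste0(sub("\\.tsv$", "", path), "_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname traceIO
#' @export
readAssayTrace <- function(path, unit = "uA/cm2") {
  d <- utils::read.delim(path)
  evPath <- paste0(sub("\\.tsv$", "", path), "_events.tsv")
  ev <- if (file.exists(evPath)) utils::read.delim(evPath)
        else data.frame(time = numeric(), agent = character(),
                        concentration = numeric())
  AssayTrace(d$time, d$value, ev, unit = unit)
}

#' Read and write DE contrast tables
#'
#' Tab-delimited with required columns `gene`, `log2fc`, `padj`,
#' `basemean`; the contrast name is stored in a `# contrast:` header line.
#'
#' @param table A [DeContrastTable-class].
#' @param path File path.
#' @return `writeDeTable` returns `path` invisibly; `readDeTable` returns
#'   a [DeContrastTable-class].
#' @name deIO
NULL

#' @rdname deIO
#' @export
writeDeTable <- function(table, path) {
  stopifnot(is(table, "DeContrastTable"))
  con <- file(path, "w")
  writeLines(paste0("# contrast: ", table@contrast), con)
  utils::write.table(contrastData(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname deIO
#' @export
readDeTable <- function(path) {
  first <- readLines(path, n = 1L)
  contrast <- if (startsWith(first, "# contrast: "))
    sub("^# contrast: ", "", first) else "unnamed"
  d <- utils::read.delim(path, comment.char = "#")
  DeContrastTable(contrast, d)
}

#' Read and write label-mask series as multi-page TIFF
#'
#' Integer label masks are stored as 16-bit pages (labels divided by
#' 65535); integer labels up to 65535 round-trip exactly.
#'
#' @param masks List of integer label matrices.
#' @param path File path of the multi-page `.tif`.
#' @return `writeLabelMasks` returns `path` invisibly; `readLabelMasks`
#'   returns the list of integer matrices.
#' @name maskIO
NULL

#' @rdname maskIO
#' @export
writeLabelMasks <- function(masks, path) {
  if (any(vapply(masks, max, numeric(1)) > 65535))
    stop("labels above 65535 cannot be stored at 16 bit", call. = FALSE)
  tiff::writeTIFF(lapply(masks, function(m) m / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname maskIO
#' @export
readLabelMasks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    m <- matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
    m
  })
}

#' Serialize planted ground truth as a structured-text sidecar
#'
#' Truth objects are written as YAML so every generated dataset carries its
#' ground truth in a plain-text, human-readable form; regeneration with the
#' same seed is byte-identical.
#'
#' @param truth A [SyntheticTruth-class].
#' @param path File path (`.yaml`).
#' @return `writeTruth` returns `path` invisibly; `readTruth` returns a
#'   [SyntheticTruth-class].
#' @name truthIO
NULL

#' @rdname truthIO
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  simplify <- function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  yaml::write_yaml(list(modality = truth@modality, seed = truth@seed,
                        truth = simplify(truth@truth)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname truthIO
#' @export
readTruth <- function(path) {
  d <- yaml::read_yaml(path)
  SyntheticTruth(d$truth, d$seed, d$modality)
}
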