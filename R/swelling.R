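#' @include AllClasses.R AllGenerics.R
NULL

#' Segment enteroids in a bright-field-derived frame
#'
#' Labels enteroid cross-sections in a single frame: automatic (Otsu)
#' thresholding for grayscale input, hole filling, connected-component
#' labeling, then removal of objects below a minimum area or circularity
#' (`4 * pi * area / perimeter^2`; irregular or lumen-collapsed objects are
#' excluded by the default floor of 0.6). Integer label masks (already
#' segmented input) skip thresholding.
#'
#' @param x 2D numeric matrix: a grayscale image, a binary mask, or an
#'   integer label mask (`isMask = TRUE` forces mask interpretation; by
#'   default any matrix whose values are all non-negative integers is
#'   treated as a mask).
#' @param minArea Minimum object area in px^2 (default 50).
#' @param minCircularity Minimum circularity in \[0, 1\] (default 0.6).
#' @param isMask Force label-mask interpretation.
#' @return data.frame with one row per object: `label`, `row`, `col`
#'   (centroid), `area` (px^2), `diameter` (equivalent circular diameter,
#'   `2 * sqrt(area / pi)`, px), `circularity`. Empty frames yield an empty
#'   data.frame with a warning.
#' @export
segmentEnteroids <- function(x, minArea = 50, minCircularity = 0.6,
                             isMask = NULL) {
  stopifnot(is.matrix(x))
  if (is.null(isMask))
    isMask <- all(x >= 0) && all(x == round(x))
  if (isMask) {
    bin <- x > 0
  } else {
    rng <- range(x)
    if (rng[2] <= rng[1]) {
      warning("constant image: no objects segmented")
      return(.emptySegmentation())
    }
    th <- EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)))
    bin <- (x - rng[1]) / diff(rng) > th
  }
  if (!any(bin)) {
    warning("no objects segmented")
    return(.emptySegmentation())
  }
  filled <- EBImage::fillHull(EBImage::Image(bin * 1))
  lab <- EBImage::bwlabel(filled)
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shp[, "s.area"]
  per <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / per^2, 1)
  keep <- area >= minArea & circ >= minCircularity
  if (!any(keep)) {
    warning("no objects passed the area/circularity filters")
    return(.emptySegmentation())
  }
  # EBImage moment features are (x, y) = (first dim, second dim) order
  data.frame(label = which(keep),
             row = unname(mom[keep, "m.cx"]),
             col = unname(mom[keep, "m.cy"]),
             area = unname(area[keep]),
             diameter = 2 * sqrt(unname(area[keep]) / pi),
             circularity = unname(circ[keep]),
             row.names = NULL)
}

.emptySegmentation <- function() {
  data.frame(label = integer(), row = numeric(), col = numeric(),
             area = numeric(), diameter = numeric(),
             circularity = numeric())
}

#' Track enteroids across frames
#'
#' Greedy nearest-centroid matching between consecutive frames with a
#' maximum-displacement gate: objects are linked to the closest object in
#' the previous frame within the gate (closest pairs linked first); objects
#' without a match within the gate start new tracks, and unmatched old
#' objects end theirs.
#'
#' @param frames List of per-frame segmentations (data.frames from
#'   [segmentEnteroids()]) or label matrices (segmented on the fly), in
#'   time order; at least 2 frames.
#' @param times Numeric timepoints, one per frame (default `0, 1, 2, ...`).
#' @param maxDisplacement Gate radius in pixels (default 15).
#' @param condition Named list of condition labels (agonist, inhibitor,
#'   dose) attached to the result.
#' @param ... Passed to [segmentEnteroids()] when frames are matrices.
#' @return An [EnteroidTrackSet-class].
#' @export
trackObjects <- function(frames, times = NULL, maxDisplacement = 15,
                         condition = list(), ...) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  segs <- lapply(frames, function(f) {
    if (is.matrix(f)) segmentEnteroids(f, ...) else f
  })
  if (is.null(times)) times <- seq_along(segs) - 1
  nextId <- 0L
  rows <- list()
  prev <- NULL
  for (k in seq_along(segs)) {
    cur <- segs[[k]]
    if (nrow(cur) == 0L) { prev <- cur; next }
    cur$id <- NA_integer_
    if (!is.null(prev) && nrow(prev) > 0L) {
      dmat <- outer(cur$row, prev$row, `-`)^2 +
              outer(cur$col, prev$col, `-`)^2
      dmat <- sqrt(dmat)
      cand <- which(dmat <= maxDisplacement, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        usedCur <- logical(nrow(cur))
        usedPrev <- logical(nrow(prev))
        for (q in seq_len(nrow(cand))) {
          i <- cand[q, 1]
          j <- cand[q, 2]
          if (usedCur[i] || usedPrev[j]) next
          cur$id[i] <- prev$id[j]
          usedCur[i] <- TRUE
          usedPrev[j] <- TRUE
        }
      }
    }
    fresh <- is.na(cur$id)
    if (any(fresh)) {
      cur$id[fresh] <- nextId + seq_len(sum(fresh))
      nextId <- nextId + sum(fresh)
    }
    rows[[k]] <- data.frame(id = cur$id, time = times[k], row = cur$row,
                            col = cur$col, area = cur$area,
                            diameter = cur$diameter)
    prev <- cur
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$id, tracks$time), ]
  rownames(tracks) <- NULL
  new("EnteroidTrackSet", tracks = tracks, condition = condition)
}

#' Diameter ratios relative to the first timepoint
#'
#' Per-track equivalent-diameter ratio `d(t) / d(t0)` at each requested
#' time — the enteroid swelling readout. Only tracks present at `t0` enter;
#' the ratio at `t0` is exactly 1.
#'
#' @param trackSet An [EnteroidTrackSet-class].
#' @param times Timepoints at which ratios are requested (default: all
#'   timepoints in the track set).
#' @param t0 Reference timepoint (default: earliest).
#' @return A [SwellingSummary-class] with per-track ratios and per-time
#'   median / interquartile-range summaries.
#' @export
diameterRatio <- function(trackSet, times = NULL, t0 = NULL) {
  stopifnot(is(trackSet, "EnteroidTrackSet"))
  tr <- trackSet@tracks
  if (is.null(t0)) t0 <- min(tr$time)
  if (is.null(times)) times <- sort(unique(tr$time))
  if (!t0 %in% tr$time) stop("no observations at t0 = ", t0, call. = FALSE)
  missing <- setdiff(times, tr$time)
  if (length(missing))
    stop("no observations at requested time(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  base <- tr[tr$time == t0, c("id", "diameter")]
  names(base)[2] <- "d0"
  out <- lapply(times, function(tp) {
    cur <- tr[tr$time == tp, c("id", "diameter")]
    m <- merge(base, cur, by = "id")
    if (nrow(m) == 0L) return(NULL)
    data.frame(id = m$id, time = tp, ratio = m$diameter / m$d0)
  })
  ratios <- do.call(rbind, out)
  smry <- do.call(rbind, lapply(split(ratios, ratios$time), function(d) {
    q <- stats::quantile(d$ratio, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(time = d$time[1], n = nrow(d), median = q[2],
               q25 = q[1], q75 = q[3], mean = mean(d$ratio))
  }))
  rownames(smry) <- NULL
  new("SwellingSummary", ratios = ratios, summary = smry)
}

#' Percent inhibition of agonist-induced swelling
#'
#' Inhibition of the swelling increment: `100 * (Rag - Rinh) / (Rag - 1)`
#' where `Rag` and `Rinh` are the group mean diameter ratios of the
#' agonist-only and agonist-plus-inhibitor arms. Defined on the increment
#' (ratio - 1) so a non-swelling enteroid contributes zero stimulated
#' secretion; undefined (error) when the agonist arm shows no swelling.
#'
#' @param ratiosAgonist Numeric vector of diameter ratios, agonist-only arm
#'   (or a [SwellingSummary-class], using all ratios at its last time).
#' @param ratiosCombined Same for the agonist + inhibitor arm.
#' @return Percent inhibition.
#' @examples
#' swellingInhibition(c(1.5, 1.5), c(1.25, 1.25))  # 50
#' @export
swellingInhibition <- function(ratiosAgonist, ratiosCombined) {
  pick <- function(x) {
    if (is(x, "SwellingSummary")) {
      r <- x@ratios
      r$ratio[r$time == max(r$time)]
    } else as.numeric(x)
  }
  a <- pick(ratiosAgonist)
  b <- pick(ratiosCombined)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ma <- mean(a)
  mb <- mean(b)
  if (ma <= 1)
    stop("agonist group shows no swelling (mean ratio <= 1); ",
         "inhibition undefined", call. = FALSE)
  100 * (ma - mb) / (ma - 1)
}
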