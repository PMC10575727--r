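#' @include AllClasses.R AllGenerics.R find-maxima.R
NULL

#' Histogram-normalize a channel
#'
#' Percentile contrast stretch to \[0, 255\]: intensities at or below the
#' lower percentile map to 0, at or above the upper percentile to 255, with
#' linear scaling in between. Applied to the DAPI channel before nuclei
#' counting. Rank order is preserved among unclipped pixels. The percentile
#' clipping (default 0.1–99.9) makes the stretch robust to hot pixels.
#'
#' @param x Numeric intensity matrix.
#' @param lower,upper Percentiles (in percent) defining the stretch window.
#' @return Matrix with values in \[0, 255\]. A constant input is returned
#'   unchanged with a warning.
#' @examples
#' normalizeHistogram(matrix(c(0, 10), 2, 2))
#' @export
normalizeHistogram <- function(x, lower = 0.1, upper = 99.9) {
  q <- stats::quantile(x, c(lower, upper) / 100, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) {
    if (max(x) > min(x)) {
      q <- range(x)   # degenerate percentiles on a near-constant image
    } else {
      warning("constant image: histogram normalization left it unchanged")
      return(x)
    }
  }
  y <- (x - q[1]) / (q[2] - q[1]) * 255
  y[y < 0] <- 0
  y[y > 255] <- 255
  y
}

#' Secretory cell-type fractions from marker maxima
#'
#' Counts nuclei on the (histogram-normalized) nuclei channel and
#' marker-positive cells on each marker channel with per-marker prominence,
#' then reports each marker count as a fraction of the nuclei count — the
#' procedure used to estimate enteroendocrine (chromogranin A) and tuft
#' (phospho-EGFR) cell fractions.
#'
#' @param image A [MultichannelImage-class].
#' @param nucleiChannel Name of the nuclei channel (default `"DAPI"`).
#' @param markerProminences Named numeric vector: marker channel name ->
#'   prominence (e.g. `c(CHGA = 100, pEGFR = 40)`).
#' @param nucleiProminence Prominence for nuclei counting (default 15,
#'   applied after histogram normalization).
#' @param normalizeNuclei Histogram-normalize the nuclei channel first
#'   (default TRUE).
#' @return data.frame with one row per marker: `marker`, `count`,
#'   `nuclei`, `fraction`, `flag` (TRUE when the fraction exceeds 1,
#'   which on sound input should not happen).
#' @export
cellTypeFractions <- function(image, nucleiChannel = "DAPI",
                              markerProminences,
                              nucleiProminence = 15,
                              normalizeNuclei = TRUE) {
  stopifnot(is(image, "MultichannelImage"))
  if (is.null(names(markerProminences)) || any(names(markerProminences) == ""))
    stop("markerProminences must be a named vector", call. = FALSE)
  nuc <- getChannel(image, nucleiChannel)
  if (normalizeNuclei) nuc <- normalizeHistogram(nuc)
  nNuc <- nMaxima(findMaxima(nuc, nucleiProminence, mask = tissueMask(image),
                             channel = nucleiChannel))
  if (nNuc == 0L)
    stop("no nuclei detected; cannot form fractions", call. = FALSE)
  counts <- vapply(names(markerProminences), function(mk) {
    nMaxima(findMaxima(image, markerProminences[[mk]], channel = mk))
  }, integer(1))
  frac <- counts / nNuc
  if (any(frac > 1))
    warning("marker count exceeds nuclei count for: ",
            paste(names(counts)[frac > 1], collapse = ", "))
  data.frame(marker = names(markerProminences), count = as.integer(counts),
             nuclei = nNuc, fraction = frac, flag = frac > 1,
             row.names = NULL)
}

#' Pairwise Pearson correlation between channels
#'
#' Computes the Pearson correlation coefficient between every pair of
#' channel intensity grids over the pixels of the tissue mask (all pixels
#' when no mask is given), summarizing marker co-occurrence across the
#' section.
#'
#' @param image A [MultichannelImage-class] with at least 2 channels.
#' @param mask Optional logical matrix overriding the image's mask.
#' @return A [ChannelCorrelationMatrix-class]. Constant channels get `NA`
#'   off-diagonal entries with a warning; drop them before clustering.
#' @export
channelCrossCorrelation <- function(image, mask = tissueMask(image)) {
  stopifnot(is(image, "MultichannelImage"))
  chn <- channelNames(image)
  if (length(chn) < 2L) stop("need at least 2 channels", call. = FALSE)
  pix <- if (is.null(mask)) TRUE else which(mask)
  mat <- vapply(chn, function(nm) getChannel(image, nm)[pix],
                numeric(if (isTRUE(pix)) length(getChannel(image, chn[1]))
                        else length(pix)))
  if (nrow(mat) < 2L) stop("need at least 2 pixels in mask", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  r <- suppressWarnings(stats::cor(mat))
  if (any(sds == 0)) {
    warning("constant channel(s): ", paste(chn[sds == 0], collapse = ", "),
            "; correlations set to NA")
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  new("ChannelCorrelationMatrix", r = r)
}

#' Hierarchically cluster a channel correlation matrix
#'
#' Agglomerative clustering of channels on the dissimilarity 1 - r, as used
#' to order channels in correlation heatmaps.
#'
#' @param x A [ChannelCorrelationMatrix-class].
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @param dropUndefined Drop channels with `NA` correlations instead of
#'   erroring (default FALSE).
#' @return The input object with the `tree` and `order` slots filled (the
#'   matrix is reordered to the leaf order).
#' @export
clusterCorrelation <- function(x, linkage = "average",
                               dropUndefined = FALSE) {
  stopifnot(is(x, "ChannelCorrelationMatrix"))
  r <- correlationMatrix(x)
  # undefined (constant) channels carry NA against every other channel
  bad <- vapply(seq_len(nrow(r)),
                function(i) all(is.na(r[i, -i])), logical(1))
  if (any(bad)) {
    if (!dropUndefined)
      stop("undefined correlations for: ",
           paste(rownames(r)[bad], collapse = ", "),
           "; drop these channels or set dropUndefined = TRUE",
           call. = FALSE)
    r <- r[!bad, !bad, drop = FALSE]
  }
  if (nrow(r) < 2L) stop("need at least 2 well-defined channels",
                         call. = FALSE)
  tree <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  ord <- tree$order
  new("ChannelCorrelationMatrix", r = r[ord, ord, drop = FALSE],
      tree = tree, order = ord)
}
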