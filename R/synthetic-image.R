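#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Channel content descriptors for synthetic multiplex images
#'
#' Build the per-channel content models consumed by
#' [syntheticImageConfig()]: `spotChannel` places isotropic Gaussian spots
#' (nuclei or scattered marker-positive cells), `ribbonChannel` places
#' dilated line segments emulating fragmented ribbon-like brush-border
#' signal with known fragment lengths, and `correlatedChannel` generates an
#' affine noisy copy of another channel with a stated Pearson target.
#'
#' @param name Channel name.
#' @param n Number of spots.
#' @param amplitude Peak intensity added by each spot / ribbon / copy.
#' @param width Gaussian sigma for spots (px); ribbon thickness (px) for
#'   ribbons.
#' @param nFragments Number of ribbon fragments.
#' @param fragmentLength Fragment length(s) in px (scalar or vector
#'   recycled over fragments).
#' @param lengthSd Gaussian jitter applied to fragment lengths (default 0).
#' @param ref Name of the reference channel being copied.
#' @param rho Target Pearson correlation with the reference, in \[-1, 1\].
#' @return A channel descriptor list for [syntheticImageConfig()].
#' @name channelDescriptors
NULL

#' @rdname channelDescriptors
#' @export
spotChannel <- function(name, n, amplitude, width = 2) {
  stopifnot(n >= 0, amplitude > 0, width > 0)
  list(name = name, type = "spots", n = n, amplitude = amplitude,
       width = width)
}

#' @rdname channelDescriptors
#' @export
ribbonChannel <- function(name, nFragments, fragmentLength, lengthSd = 0,
                          amplitude = 120, width = 3) {
  stopifnot(nFragments >= 0, all(fragmentLength > 0), lengthSd >= 0,
            amplitude > 0, width >= 1)
  list(name = name, type = "ribbons", n = nFragments,
       length = fragmentLength, lengthSd = lengthSd,
       amplitude = amplitude, width = width)
}

#' @rdname channelDescriptors
#' @export
correlatedChannel <- function(name, ref, rho, amplitude = 100) {
  if (rho < -1 || rho > 1)
    stop("requested correlation must lie in [-1, 1]", call. = FALSE)
  list(name = name, type = "correlated", ref = ref, rho = rho,
       amplitude = amplitude)
}

#' Configuration for the synthetic multiplex-image generator
#'
#' @param channels List of channel descriptors (see
#'   [channelDescriptors]).
#' @param size Image size in pixels, `c(rows, cols)`.
#' @param background Background intensity added to every channel.
#' @param noiseSd Standard deviation of the additive Gaussian noise
#'   (clipped at zero, matching background-corrected fluorescence); >= 0.
#' @param noiseCorrelation Gaussian blur sigma (px) applied to the noise
#'   field before adding it, emulating the optical band-limiting of real
#'   microscope noise (0 = independent pixel noise; default 1). The
#'   marginal noise sd is rescaled to `noiseSd` after blurring.
#' @param seed Integer seed.
#' @return Validated config list of class `"syntheticImageConfig"`.
#' @export
syntheticImageConfig <- function(channels, size = c(256, 256),
                                 background = 5, noiseSd = 1,
                                 noiseCorrelation = 1, seed = 1) {
  if (any(size <= 0)) stop("sizes must be positive", call. = FALSE)
  if (noiseSd < 0) stop("noise sd must be >= 0", call. = FALSE)
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate channel names", call. = FALSE)
  structure(list(channels = channels, size = as.integer(size),
                 background = background, noiseSd = noiseSd,
                 noiseCorrelation = noiseCorrelation,
                 seed = as.integer(seed)),
            class = "syntheticImageConfig")
}

# Sample n integer centers with pairwise separation > minSep, uniform over
# [margin, dim - margin]; bounded retries.
.placeCenters <- function(n, size, margin, minSep, retries = 500) {
  centers <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retries)) {
      r <- sample(seq(margin, size[1] - margin), 1)
      cc <- sample(seq(margin, size[2] - margin), 1)
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1] - r)^2 + (centers[, 2] - cc)^2)) > minSep) {
        centers <- rbind(centers, c(r, cc))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place spot ", k, " without crowding after ",
           retries, " retries", call. = FALSE)
  }
  colnames(centers) <- c("row", "col")
  centers
}

.renderSpots <- function(grid, centers, amplitude, sigma) {
  R <- ceiling(4 * sigma)
  nr <- nrow(grid)
  nc <- ncol(grid)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]
    c0 <- centers[k, 2]
    rs <- max(1, r0 - R):min(nr, r0 + R)
    cs <- max(1, c0 - R):min(nc, c0 + R)
    g <- outer((rs - r0)^2, (cs - c0)^2, `+`)
    grid[rs, cs] <- grid[rs, cs] + amplitude * exp(-g / (2 * sigma^2))
  }
  grid
}

.rasterizeSegment <- function(p0, p1, nr, nc, width) {
  L <- sqrt(sum((p1 - p0)^2))
  tt <- seq(0, 1, length.out = max(2L, ceiling(2 * L) + 1L))
  pts <- unique(cbind(round(p0[1] + tt * (p1[1] - p0[1])),
                      round(p0[2] + tt * (p1[2] - p0[2]))))
  rad <- floor(width / 2)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 1e-9, ]
  out <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    cbind(pts[, 1] + offs$dr[i], pts[, 2] + offs$dc[i])
  })))
  out[out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= nc, ,
      drop = FALSE]
}

#' Generate a synthetic multiplex immunofluorescence image
#'
#' Renders every configured channel (Gaussian spots, dilated ribbon
#' fragments, correlated copies), adds background and zero-clipped Gaussian
#' noise, and returns the image together with the planted ground truth
#' (spot centers, fragment endpoints and Euclidean lengths, correlation
#' targets). Generation is fully determined by the config seed.
#'
#' @param config A [syntheticImageConfig()].
#' @return List with elements `image` ([MultichannelImage-class]) and
#'   `truth` ([SyntheticTruth-class]).
#' @export
genMxifImage <- function(config) {
  stopifnot(inherits(config, "syntheticImageConfig"))
  withr::with_seed(config$seed, {
    size <- config$size
    clean <- list()
    truth <- list()
    for (ch in config$channels) {
      grid <- matrix(0, size[1], size[2])
      if (ch$type == "spots") {
        if (ch$n > 0) {
          margin <- ceiling(4 * ch$width) + 1
          centers <- .placeCenters(ch$n, size, margin,
                                   minSep = 6 * ch$width + 2)
          grid <- .renderSpots(grid, centers, ch$amplitude, ch$width)
        } else centers <- matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("row", "col")))
        truth[[ch$name]] <- list(type = "spots", centers = centers,
                                 amplitude = ch$amplitude)
      } else if (ch$type == "ribbons") {
        lens <- rep_len(ch$length, ch$n)
        if (ch$lengthSd > 0)
          lens <- pmax(4, lens + stats::rnorm(ch$n, 0, ch$lengthSd))
        placedPix <- matrix(numeric(0), ncol = 2)
        endpoints <- matrix(numeric(0), ncol = 4)
        for (k in seq_len(ch$n)) {
          ok <- FALSE
          for (try in seq_len(200)) {
            L <- lens[k]
            margin <- L / 2 + ch$width + 2
            if (margin * 2 >= min(size))
              stop("fragment length ", L, " does not fit the image",
                   call. = FALSE)
            ctr <- c(stats::runif(1, margin, size[1] - margin),
                     stats::runif(1, margin, size[2] - margin))
            th <- stats::runif(1, 0, pi)
            half <- (L / 2) * c(cos(th), sin(th))
            p0 <- ctr - half
            p1 <- ctr + half
            pix <- .rasterizeSegment(p0, p1, size[1], size[2], ch$width)
            if (nrow(placedPix) == 0L ||
                min(sqrt(outer(pix[, 1], placedPix[, 1], `-`)^2 +
                         outer(pix[, 2], placedPix[, 2], `-`)^2)) >
                  ch$width + 2) {
              grid[cbind(pix[, 1], pix[, 2])] <- ch$amplitude
              placedPix <- rbind(placedPix, pix)
              endpoints <- rbind(endpoints, c(p0, p1))
              ok <- TRUE
              break
            }
          }
          if (!ok)
            stop("could not place ribbon fragment ", k,
                 " without overlap after 200 retries", call. = FALSE)
        }
        colnames(endpoints) <- c("row0", "col0", "row1", "col1")
        truth[[ch$name]] <- list(
          type = "ribbons", endpoints = endpoints,
          lengths = if (nrow(endpoints))
            sqrt((endpoints[, 3] - endpoints[, 1])^2 +
                 (endpoints[, 4] - endpoints[, 2])^2) else numeric(0))
      } else if (ch$type == "correlated") {
        base <- clean[[ch$ref]]
        if (is.null(base))
          stop("correlated channel '", ch$name, "' references unknown or ",
               "later channel '", ch$ref, "'", call. = FALSE)
        z <- as.vector(scale(as.vector(base)))
        if (any(is.na(z))) z <- rep(0, length(base))
        mix <- ch$rho * z +
          sqrt(1 - ch$rho^2) * stats::rnorm(length(z))
        # affine rescale into [0, amplitude]: preserves the Pearson target
        # exactly and avoids zero-clipping of the anticorrelated tail
        rng <- range(mix)
        if (rng[2] > rng[1]) mix <- (mix - rng[1]) / (rng[2] - rng[1])
        grid <- matrix(ch$amplitude * mix, size[1], size[2])
        truth[[ch$name]] <- list(type = "correlated", ref = ch$ref,
                                 rho = ch$rho)
      } else stop("unknown channel type: ", ch$type, call. = FALSE)
      clean[[ch$name]] <- grid
    }
    noisy <- lapply(clean, function(g) {
      g <- g + config$background
      if (config$noiseSd > 0) {
        nz <- matrix(stats::rnorm(length(g)), nrow(g), ncol(g))
        if (config$noiseCorrelation > 0) {
          nz <- as.matrix(EBImage::gblur(EBImage::Image(nz),
                                         sigma = config$noiseCorrelation))
          nz <- nz / stats::sd(nz)
        }
        g <- g + config$noiseSd * nz
      }
      pmax(g, 0)
    })
    list(image = MultichannelImage(noisy),
         truth = SyntheticTruth(truth, config$seed, "mxif"))
  })
}

#' Configuration for the synthetic enteroid-swelling series
#'
#' Defaults encode the study conditions: forskolin drives the mean enteroid
#' diameter ratio to 1.4 after 1 h in both healthy and MVID enteroids, and
#' crofelemer co-treatment inhibits the swelling increment by 40\%
#' (healthy) or 50\% (MVID).
#'
#' @param condition `"healthy"` or `"mvid"`; selects the default crofelemer
#'   inhibition (40 and 50 percent respectively).
#' @param arm `"agonist"` (forskolin only) or `"agonist_inhibitor"`
#'   (forskolin + crofelemer).
#' @param nObjects Number of enteroids (default 20).
#' @param times Timepoints in seconds (first is t0; default 0 and 3600).
#' @param diameterRatios True mean diameter ratio at each timepoint for the
#'   agonist-only protocol (first must be 1; default `c(1, 1.4)`).
#' @param areaGrowthFactors Alternative to `diameterRatios`: true area
#'   growth factors (ratios are their square roots).
#' @param inhibition Percent inhibition of the swelling increment applied
#'   in the inhibitor arm (default by condition).
#' @param objectSd Relative between-object jitter of the swelling increment
#'   (default 0.05).
#' @param size Frame size in px (default 512 x 512).
#' @param radiusRange Initial radius range in px (default 15-25).
#' @param seed Integer seed.
#' @return Config list of class `"syntheticSwellingConfig"`.
#' @export
syntheticSwellingConfig <- function(condition = c("healthy", "mvid"),
                                    arm = c("agonist", "agonist_inhibitor"),
                                    nObjects = 20, times = c(0, 3600),
                                    diameterRatios = NULL,
                                    areaGrowthFactors = NULL,
                                    inhibition = NULL, objectSd = 0.05,
                                    size = c(512, 512),
                                    radiusRange = c(15, 25), seed = 1) {
  condition <- match.arg(condition)
  arm <- match.arg(arm)
  if (!is.null(areaGrowthFactors)) diameterRatios <- sqrt(areaGrowthFactors)
  if (is.null(diameterRatios))
    diameterRatios <- c(1, rep(1.4, length(times) - 1))
  if (length(diameterRatios) != length(times) ||
      abs(diameterRatios[1] - 1) > 1e-12)
    stop("diameterRatios must align with times and start at 1",
         call. = FALSE)
  if (is.null(inhibition))
    inhibition <- if (condition == "healthy") 40 else 50
  if (any(size <= 0) || nObjects < 1 || any(radiusRange <= 0))
    stop("sizes, object count and radii must be positive", call. = FALSE)
  structure(list(condition = condition, arm = arm, nObjects = nObjects,
                 times = times, diameterRatios = diameterRatios,
                 inhibition = inhibition, objectSd = objectSd,
                 size = as.integer(size), radiusRange = radiusRange,
                 seed = as.integer(seed)),
            class = "syntheticSwellingConfig")
}

#' Generate a synthetic enteroid swelling series
#'
#' Places non-overlapping disks and grows each one so that its equivalent
#' diameter follows the configured (per-object jittered) diameter-ratio
#' schedule; the inhibitor arm scales the swelling increment down by the
#' configured inhibition percentage. Returns noise-free integer label masks
#' per timepoint plus the planted growth truth.
#'
#' @param config A [syntheticSwellingConfig()].
#' @return List with `masks` (list of integer label matrices), `times`, and
#'   `truth` ([SyntheticTruth-class] holding per-object centers, initial
#'   radii, true per-time diameter ratios and area growth factors).
#' @export
genSwellingSeries <- function(config) {
  stopifnot(inherits(config, "syntheticSwellingConfig"))
  withr::with_seed(config$seed, {
    ratios <- config$diameterRatios
    if (config$arm == "agonist_inhibitor")
      ratios <- 1 + (ratios - 1) * (1 - config$inhibition / 100)
    r0 <- stats::runif(config$nObjects, config$radiusRange[1],
                       config$radiusRange[2])
    jit <- pmax(0, stats::rnorm(config$nObjects, 1, config$objectSd))
    perObj <- t(vapply(seq_len(config$nObjects), function(i) {
      1 + (ratios - 1) * jit[i]
    }, numeric(length(ratios))))
    maxR <- r0 * apply(perObj, 1, max)
    size <- config$size
    centers <- matrix(NA_real_, config$nObjects, 2)
    for (i in seq_len(config$nObjects)) {
      lim <- ceiling(maxR[i]) + 2
      if (2 * lim >= min(size))
        stop("object ", i, " would overflow the image bounds",
             call. = FALSE)
      ok <- FALSE
      for (try in seq_len(500)) {
        p <- c(stats::runif(1, lim, size[1] - lim),
               stats::runif(1, lim, size[2] - lim))
        if (i == 1L || all(sqrt((centers[seq_len(i - 1), 1] - p[1])^2 +
                                (centers[seq_len(i - 1), 2] - p[2])^2) >
                           maxR[seq_len(i - 1)] + maxR[i] + 4)) {
          centers[i, ] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place disk ", i, " without overlap", call. = FALSE)
    }
    rowIdx <- matrix(rep(seq_len(size[1]), size[2]), size[1])
    colIdx <- matrix(rep(seq_len(size[2]), each = size[1]), size[1])
    masks <- lapply(seq_along(config$times), function(tk) {
      m <- matrix(0L, size[1], size[2])
      for (i in seq_len(config$nObjects)) {
        rad <- r0[i] * perObj[i, tk]
        sel <- (rowIdx - centers[i, 1])^2 + (colIdx - centers[i, 2])^2 <=
          rad^2
        m[sel] <- i
      }
      m
    })
    truth <- list(centers = centers, r0 = r0,
                  diameterRatios = perObj,
                  areaGrowthFactors = perObj^2,
                  meanDiameterRatios = colMeans(perObj),
                  times = config$times, arm = config$arm,
                  condition = config$condition,
                  inhibition = config$inhibition)
    list(masks = masks, times = config$times,
         truth = SyntheticTruth(truth, config$seed, "swelling"))
  })
}
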