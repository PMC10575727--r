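#' @include AllClasses.R AllGenerics.R utils.R
NULL

.shiftMat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Zhang-Suen iterative thinning of a binary mask to a one-pixel-wide,
# 8-connected skeleton. Row index increases downward; P2..P9 run clockwise
# from the north neighbour.
.thinZS <- function(mask) {
  m <- mask
  offs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) .shiftMat(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8) 1 else k + 1
        A <- A + (!P[[k]] & P[[nxt]])
      }
      if (step == 1) {
        c1 <- !(P[[1]] & P[[3]] & P[[5]])
        c2 <- !(P[[3]] & P[[5]] & P[[7]])
      } else {
        c1 <- !(P[[1]] & P[[3]] & P[[7]])
        c2 <- !(P[[1]] & P[[5]] & P[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Remove spur branches shorter than minBranch pixels: walk from each
# endpoint (degree 1) through degree-2 pixels; if a junction (degree >= 3)
# is reached before minBranch pixels, delete the walked path. Repeats until
# stable. A simple open curve (endpoint to endpoint) is never pruned here;
# whole components below the length floor are dropped by the caller.
.pruneSpurs <- function(idx, nr, nc, minBranch) {
  repeat {
    if (length(idx) == 0L) return(idx)
    deg <- .degree8(idx, nr, nc)
    inset <- logical(nr * nc)
    inset[idx] <- TRUE
    degAt <- integer(nr * nc)
    degAt[idx] <- deg
    endpoints <- idx[deg == 1L]
    if (length(endpoints) == 0L) return(idx)
    removed <- integer(0)
    for (e in endpoints) {
      if (!inset[e]) next
      path <- e
      prev <- 0L
      cur <- e
      hitJunction <- FALSE
      repeat {
        r <- ((cur - 1L) %% nr) + 1L
        cc <- ((cur - 1L) %/% nr) + 1L
        nbrs <- integer(0)
        for (dr in -1L:1L) for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr
          ccn <- cc + dc
          if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
          j <- cur + dr + dc * nr
          if (inset[j] && j != prev) nbrs <- c(nbrs, j)
        }
        if (length(nbrs) == 0L) break            # isolated path end
        nxt <- nbrs[1L]
        if (degAt[nxt] >= 3L) { hitJunction <- TRUE; break }
        if (length(nbrs) > 1L) { hitJunction <- TRUE; break }
        path <- c(path, nxt)
        if (degAt[nxt] == 1L) break              # other endpoint: open curve
        prev <- cur
        cur <- nxt
        if (length(path) >= minBranch) break
      }
      if (hitJunction && length(path) < minBranch) {
        inset[path] <- FALSE
        removed <- c(removed, path)
        # the junction pixel itself is a spur stub when its remaining
        # neighbours stay mutually connected without it (e.g. a spur
        # meeting a straight run by diagonal contact); drop it too
        jpix <- nxt
        if (inset[jpix] && .isRedundantPixel(jpix, inset, nr, nc)) {
          inset[jpix] <- FALSE
          removed <- c(removed, jpix)
        }
      }
    }
    if (length(removed) == 0L) return(idx)
    idx <- idx[!idx %in% removed]
  }
}

# TRUE when the in-set neighbours of pixel j form one 8-connected group
# among themselves, so removing j cannot disconnect the skeleton locally.
.isRedundantPixel <- function(j, inset, nr, nc) {
  r <- ((j - 1L) %% nr) + 1L
  cc <- ((j - 1L) %/% nr) + 1L
  nbrs <- matrix(integer(0), ncol = 2)
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr
    ccn <- cc + dc
    if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
    if (inset[j + dr + dc * nr]) nbrs <- rbind(nbrs, c(rr, ccn))
  }
  n <- nrow(nbrs)
  if (n < 2L) return(FALSE)
  seen <- c(1L)
  repeat {
    added <- FALSE
    for (k in seq_len(n)) {
      if (k %in% seen) next
      if (any(abs(nbrs[k, 1] - nbrs[seen, 1]) <= 1L &
              abs(nbrs[k, 2] - nbrs[seen, 2]) <= 1L)) {
        seen <- c(seen, k)
        added <- TRUE
      }
    }
    if (!added) break
  }
  length(seen) == n
}

#' Threshold, binarize and skeletonize a marker channel
#'
#' Reduces a ribbon-like marker signal (e.g. the CD10 brush-border stain) to
#' one-pixel-wide curve skeletons: automatic (Otsu) or fixed thresholding,
#' Zhang-Suen thinning, then pruning of side branches shorter than a
#' minimum branch length (default 10 px) to avoid background, and removal of
#' components shorter in total than that minimum.
#'
#' @param x Numeric intensity matrix, or a [MultichannelImage-class]
#'   together with `channel`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Required when `method = "fixed"`: pixels strictly above
#'   it are foreground.
#' @param minBranchLength Minimum branch/component length in pixels
#'   (default 10).
#' @param channel Channel name when `x` is a `MultichannelImage`.
#' @return A [SkeletonSet-class]. An empty foreground yields an empty set
#'   with a warning.
#' @export
skeletonizeMarker <- function(x, method = c("otsu", "fixed"),
                              threshold = NULL, minBranchLength = 10,
                              channel = "channel") {
  if (is(x, "MultichannelImage")) {
    img <- getChannel(x, channel)
  } else {
    img <- x
  }
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(img)
    if (rng[2] <= rng[1])
      stop("constant image: automatic threshold undefined", call. = FALSE)
    th01 <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)))
    threshold <- rng[1] + th01 * diff(rng)
  } else if (is.null(threshold)) {
    stop("method = 'fixed' requires a threshold", call. = FALSE)
  }
  fg <- img > threshold
  if (!any(fg)) {
    warning("empty foreground after thresholding; returning empty skeleton set")
    return(new("SkeletonSet", components = list(), channel = channel,
               threshold = threshold, minBranchLength = minBranchLength,
               dim = dim(img)))
  }
  sk <- .thinZS(fg)
  idx <- which(sk)
  nr <- nrow(img)
  nc <- ncol(img)
  idx <- .pruneSpurs(idx, nr, nc, minBranchLength)
  comps <- list()
  if (length(idx)) {
    lab <- .label8(idx, nr, nc)
    for (k in sort(unique(lab))) {
      sub <- idx[lab == k]
      if (length(sub) < max(2L, minBranchLength)) next
      comps[[length(comps) + 1L]] <- .idxToRc(sub, nr)
    }
  }
  if (length(comps) == 0L)
    warning("no skeleton component survived pruning")
  new("SkeletonSet", components = comps, channel = channel,
      threshold = threshold, minBranchLength = minBranchLength,
      dim = dim(img))
}

#' Maximum Feret (caliper) distance per skeleton component
#'
#' For each skeleton component, the largest Euclidean distance between any
#' two member pixel centres — the maximum caliper of the Feret distance.
#' Longer calipers indicate more continuous brush-border ribbons; the
#' per-image mean is the continuity score. Computed exactly via the convex
#' hull of each component.
#'
#' @param skeletons A non-empty [SkeletonSet-class].
#' @param pixelSize Micrometres per pixel; when given, calipers are also
#'   reported in micrometres.
#' @return A [FeretSummary-class].
#' @export
feretDistances <- function(skeletons, pixelSize = NA_real_) {
  stopifnot(is(skeletons, "SkeletonSet"))
  comps <- skeletonComponents(skeletons)
  if (length(comps) == 0L)
    stop("empty SkeletonSet: the upstream skeletonization warned that no ",
         "component survived; nothing to measure", call. = FALSE)
  cal <- vapply(comps, function(p) {
    p <- unique(p)
    if (nrow(p) == 2L) return(sqrt(sum((p[1, ] - p[2, ])^2)))
    h <- tryCatch(grDevices::chull(p[, 2], p[, 1]), error = function(e) NULL)
    q <- if (is.null(h) || length(h) < 2L) p else p[h, , drop = FALSE]
    max(stats::dist(q))
  }, numeric(1))
  per <- data.frame(component = seq_along(cal), caliper_px = cal)
  if (!is.na(pixelSize)) per$caliper_um <- cal * pixelSize
  new("FeretSummary", perComponent = per, pixelSize = as.numeric(pixelSize))
}
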