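#' @include AllClasses.R AllGenerics.R
NULL

# Persistence of every regional maximum of an intensity grid, computed by a
# single union-find sweep over pixels in decreasing intensity order
# (lexicographic linear-index tie-break). A maximum's prominence is its peak
# value minus the level at which its superlevel-set component first touches a
# component holding a higher peak (equal peaks: the plateau whose smallest
# linear index is smaller dominates). A maximum never dominated keeps
# prominence peak - (minimum value in its connected component).
#
# Returns a data.frame with one row per regional maximum: `rep` (smallest
# linear index of the peak plateau), `peak`, `prominence`.
.maximaPersistence <- function(img, mask = NULL) {
  nr <- nrow(img)
  nc <- ncol(img)
  n <- nr * nc
  idx <- if (is.null(mask)) seq_len(n) else which(mask)
  if (length(idx) == 0L)
    return(data.frame(rep = integer(), peak = numeric(),
                      prominence = numeric()))
  v <- img[idx]
  ord <- order(-v, idx)
  sidx <- idx[ord]
  sval <- v[ord]

  parent <- integer(n)           # 0 = not yet processed
  peakV <- numeric(n)
  peakR <- integer(n)
  minV <- numeric(n)

  m <- length(sidx)
  drep <- integer(m)
  dpeak <- numeric(m)
  dprom <- numeric(m)
  ndead <- 0L

  nb <- integer(8)
  for (k in seq_len(m)) {
    i <- sidx[k]
    vv <- sval[k]
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    nn <- 0L
    for (dr in -1L:1L) {
      rr <- r + dr
      if (rr < 1L || rr > nr) next
      for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        ccn <- cc + dc
        if (ccn < 1L || ccn > nc) next
        j <- i + dr + dc * nr
        if (parent[j] == 0L) next
        # find root with path halving
        while (parent[j] != j) {
          parent[j] <- parent[parent[j]]
          j <- parent[j]
        }
        dup <- FALSE
        if (nn > 0L) for (q in seq_len(nn)) if (nb[q] == j) { dup <- TRUE; break }
        if (!dup) { nn <- nn + 1L; nb[nn] <- j }
      }
    }
    if (nn == 0L) {
      parent[i] <- i
      peakV[i] <- vv
      peakR[i] <- i
      minV[i] <- vv
    } else {
      win <- nb[1L]
      if (nn > 1L) for (q in 2L:nn) {
        cand <- nb[q]
        if (peakV[cand] > peakV[win] ||
            (peakV[cand] == peakV[win] && peakR[cand] < peakR[win]))
          win <- cand
      }
      if (nn > 1L) for (q in seq_len(nn)) {
        lose <- nb[q]
        if (lose == win) next
        prom <- peakV[lose] - vv
        if (prom > 0) {
          ndead <- ndead + 1L
          drep[ndead] <- peakR[lose]
          dpeak[ndead] <- peakV[lose]
          dprom[ndead] <- prom
        }
        parent[lose] <- win
      }
      parent[i] <- win
      minV[win] <- vv
    }
  }

  alive <- which(parent[sidx] == sidx)
  arep <- peakR[sidx[alive]]
  apeak <- peakV[sidx[alive]]
  aprom <- apeak - minV[sidx[alive]]
  out <- data.frame(
    rep = c(drep[seq_len(ndead)], arep),
    peak = c(dpeak[seq_len(ndead)], apeak),
    prominence = c(dprom[seq_len(ndead)], aprom))
  out[order(out$rep), , drop = FALSE]
}

# Representative point of a peak plateau: the connected equal-valued region
# containing `rep`, reduced to the member pixel nearest the plateau centroid
# (ties broken by row, then column).
.plateauPoint <- function(img, rep, peak, mask, nr, nc) {
  inmask <- function(j) is.null(mask) || mask[j]
  seen <- integer(0)
  queue <- rep
  visited <- new.env(hash = TRUE, size = 64L)
  assign(as.character(rep), TRUE, envir = visited)
  while (length(queue)) {
    j <- queue[[1L]]
    queue <- queue[-1L]
    seen <- c(seen, j)
    r <- ((j - 1L) %% nr) + 1L
    cc <- ((j - 1L) %/% nr) + 1L
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr
      ccn <- cc + dc
      if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
      jj <- j + dr + dc * nr
      key <- as.character(jj)
      if (!is.null(visited[[key]])) next
      if (img[jj] == peak && inmask(jj)) {
        assign(key, TRUE, envir = visited)
        queue <- c(queue, jj)
      }
    }
  }
  rc <- .idxToRc(seen, nr)
  ctr <- colMeans(rc)
  d2 <- (rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2
  best <- which(d2 == min(d2))
  if (length(best) > 1L) {
    sub <- rc[best, , drop = FALSE]
    best <- best[order(sub[, 1], sub[, 2])[1L]]
  }
  rc[best, ]
}

#' Find prominence-filtered local maxima
#'
#' Counts regional maxima of a fluorescence channel that stand out from
#' their surroundings by more than a prominence threshold, the operation
#' used to count nuclei (prominence 15 on the histogram-normalized DAPI
#' channel) and marker-positive cells (prominence 40 or 100). Semantics are
#' h-maxima: a regional maximum is accepted when its peak exceeds the level
#' at which its superlevel-set component merges with a component holding a
#' higher peak by strictly more than `prominence`; a maximum with no higher
#' competitor in its connected component is measured against the component
#' minimum. Plateau maxima yield one point, the plateau pixel nearest the
#' plateau centroid (ties broken by row, then column order).
#'
#' @param x A numeric matrix (intensity grid) or a
#'   [MultichannelImage-class].
#' @param prominence Positive prominence, in intensity units.
#' @param mask Optional logical matrix restricting the search; for a
#'   `MultichannelImage` the image's own tissue mask is used by default.
#' @param channel Channel name (required for `MultichannelImage` input).
#' @param ... Passed between methods.
#' @return A [MaximaResult-class] object.
#' @examples
#' m <- matrix(0, 16, 16)
#' m[5, 5] <- 100
#' nMaxima(findMaxima(m, prominence = 15))
#' @export
setGeneric("findMaxima",
           function(x, prominence, ...) standardGeneric("findMaxima"))

#' @rdname findMaxima
setMethod("findMaxima", "matrix",
  function(x, prominence, mask = NULL, channel = "channel") {
    if (!is.numeric(prominence) || length(prominence) != 1L ||
        is.na(prominence) || prominence <= 0)
      stop("prominence must be a single positive number", call. = FALSE)
    pers <- .maximaPersistence(x, mask)
    keep <- pers[pers$prominence > prominence, , drop = FALSE]
    nr <- nrow(x)
    if (nrow(keep)) {
      pts <- t(vapply(seq_len(nrow(keep)), function(i) {
        .plateauPoint(x, keep$rep[i], keep$peak[i], mask, nr, ncol(x))
      }, numeric(2)))
    } else {
      pts <- matrix(integer(0), ncol = 2)
    }
    colnames(pts) <- c("row", "col")
    new("MaximaResult", channel = channel, prominence = prominence,
        coords = pts)
  })

#' @rdname findMaxima
setMethod("findMaxima", "MultichannelImage",
  function(x, prominence, channel, mask = tissueMask(x)) {
    findMaxima(getChannel(x, channel), prominence, mask = mask,
               channel = channel)
  })
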