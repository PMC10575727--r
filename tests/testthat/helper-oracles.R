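# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package:
# connected components come from igraph, and prominences are found by
# explicit threshold descent over the unique intensity levels.

# Label the active pixels of an nr x nc grid (8-connectivity) with igraph.
oracle_label <- function(active, nr, nc) {
  idx <- which(active)
  if (length(idx) == 0L) return(integer(0))
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ok <- r + off[1] >= 1L & r + off[1] <= nr & cc + off[2] <= nc &
      cc + off[2] >= 1L
    nbi <- idx[ok] + off[1] + off[2] * nr
    hit <- active[nbi]
    if (any(hit))
      edges <- rbind(edges, cbind(vid[idx[ok][hit]], vid[nbi[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  out <- integer(nr * nc)
  out[idx] <- comp
  out
}

# Brute-force h-maxima counting: regional maxima by direct neighbour
# inspection, prominence by threshold descent over unique levels. Dominance
# uses peak value, ties broken by the smallest linear index of the peak
# plateau. Returns plateau representative indices (sorted) of all maxima
# with prominence strictly above h.
oracle_hmaxima <- function(img, h, mask = NULL) {
  nr <- nrow(img)
  nc <- ncol(img)
  active <- matrix(TRUE, nr, nc)
  if (!is.null(mask)) active <- mask
  work <- img
  work[!active] <- -Inf

  # regional maxima: equal-value plateaus with no higher active neighbour
  plateauLab <- integer(nr * nc)
  reps <- integer(0)
  peaks <- numeric(0)
  for (v in unique(work[active])) {
    lab <- oracle_label(active & work == v, nr, nc)
    for (k in setdiff(unique(lab), 0L)) {
      pix <- which(lab == k)
      higher <- FALSE
      for (j in pix) {
        r <- ((j - 1L) %% nr) + 1L
        cc <- ((j - 1L) %/% nr) + 1L
        for (dr in -1L:1L) for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr
          ccn <- cc + dc
          if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
          if (work[j + dr + dc * nr] > v) higher <- TRUE
        }
        if (higher) break
      }
      if (!higher) {
        reps <- c(reps, min(pix))
        peaks <- c(peaks, v)
      }
    }
  }
  if (length(reps) == 0L) return(integer(0))

  levels <- sort(unique(work[active]), decreasing = TRUE)
  death <- rep(NA_real_, length(reps))
  for (L in levels) {
    lab <- oracle_label(active & work >= L, nr, nc)
    comps <- lab[reps]
    for (i in seq_along(reps)) {
      if (!is.na(death[i]) || peaks[i] < L) next
      same <- which(comps == comps[i])
      dom <- any(peaks[same] > peaks[i] |
                 (peaks[same] == peaks[i] & reps[same] < reps[i]))
      if (dom) death[i] <- L
    }
  }
  prom <- peaks - death
  never <- is.na(death)
  if (any(never)) {
    lab <- oracle_label(active & is.finite(work), nr, nc)
    for (i in which(never))
      prom[i] <- peaks[i] - min(work[active & lab == lab[reps[i]]])
  }
  sort(reps[prom > h])
}

# Plateau representatives (smallest linear index of the accepted peak
# plateaus) from a MaximaResult, for comparison against oracle_hmaxima.
impl_maxima_reps <- function(img, h, mask = NULL) {
  pers <- enteroquant:::.maximaPersistence(img, mask)
  sort(pers$rep[pers$prominence > h])
}

# All-pairs Feret caliper.
oracle_feret <- function(pts) {
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Row-by-row rescue predicate oracle (rows aligned by gene id once, then a
# scalar predicate applied per row).
oracle_rescue <- function(baselineDf, treatmentDf, cutoff = 0.05) {
  shared <- intersect(baselineDf$gene, treatmentDf$gene)
  b <- baselineDf[match(shared, baselineDf$gene), ]
  t <- treatmentDf[match(shared, treatmentDf$gene), ]
  hits <- character(0)
  for (i in seq_along(shared)) {
    if (is.na(b$padj[i]) || is.na(t$padj[i])) next
    if (b$padj[i] < cutoff && t$padj[i] < cutoff &&
        b$log2fc[i] != 0 && t$log2fc[i] != 0 &&
        sign(b$log2fc[i]) != sign(t$log2fc[i]))
      hits <- c(hits, shared[i])
  }
  sort(hits)
}

# Random quantized test grid: smoothed integer terrain with plateaus.
random_grid <- function(seed, nr = 64, nc = 64, levels = 16) {
  withr::with_seed(seed, {
    matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc)
  })
}

skeleton_from_points <- function(pts, dim = c(64L, 64L)) {
  new("SkeletonSet", components = list(pts), channel = "test",
      threshold = 0, minBranchLength = 0, dim = dim)
}

# Random connected skeleton-like component: a lattice random walk.
random_walk_component <- function(seed, n = 120, nr = 400, nc = 400) {
  withr::with_seed(seed, {
    pos <- c(sample(100:300, 1), sample(100:300, 1))
    pts <- matrix(pos, 1)
    for (k in seq_len(n - 1)) {
      step <- sample(list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0),
                          c(1, 1), c(-1, -1), c(1, -1), c(-1, 1)), 1)[[1]]
      pos <- pmin(pmax(pos + step, 1), c(nr, nc))
      pts <- rbind(pts, pos)
    }
    unique(pts)
  })
}
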