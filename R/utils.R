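`%||%` <- function(a, b) if (is.null(a)) b else a

# 8-connected labeling of a sparse pixel set given as linear indices into an
# nr x nc grid. Returns an integer component id per input index.
.label8 <- function(idx, nr, nc) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    if (!any(ok)) next
    nb <- integer(n)
    nb[ok] <- pos[idx[ok] + dr + dc * nr]
    hit <- which(nb > 0L)
    for (i in hit) {
      a <- findRoot(i)
      b <- findRoot(nb[i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  match(roots, sort(unique(roots)))
}

# Degree of each skeleton pixel (number of 8-neighbours inside the set).
.degree8 <- function(idx, nr, nc) {
  inset <- logical(nr * nc)
  inset[idx] <- TRUE
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  deg <- integer(length(idx))
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nbi <- idx[ok] + dr + dc * nr
    deg[ok] <- deg[ok] + inset[nbi]
  }
  deg
}

.idxToRc <- function(idx, nr) {
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

.rcToIdx <- function(r, cc, nr) (cc - 1L) * nr + r
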