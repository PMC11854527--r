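# Independent brute-force oracles and small builders used across the suite.

# Build a ParticleEnsemble directly from positions/features.
makeEnsemble <- function(pos, feat = rep(0.5, nrow(pos)),
                         dim = c(2L, as.integer(ceiling(nrow(pos) / 2))),
                         spacing = 0.1) {
  new("ParticleEnsemble", positions = pos, features = feat,
      pixelIndex = seq_len(nrow(pos)), dim = as.integer(dim),
      spacing = spacing)
}

# Lattice ensemble of an image-like constant-feature grid.
latticeEnsemble <- function(h, w, feat = 0.5) {
  g <- makePixelGrid(h, w)
  makeEnsemble(g@positions, rep(feat, h * w), dim = c(h, w),
               spacing = g@spacing)
}

# Random 0/1 mask with at least one fg and one bg pixel.
randomMask <- function(nr, nc, pFg = 0.4) {
  repeat {
    m <- matrix(as.integer(runif(nr * nc) < pFg), nr, nc)
    if (any(m == 1L) && any(m == 0L)) return(m)
  }
}

# Brute-force Surface Dice: explicit boundary scan + all-pairs distances.
bruteSurfaceDice <- function(g, t, tau) {
  boundary <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (m[i, j] != 1L) next
      nb <- c(if (i > 1) m[i - 1, j] else 0L,
              if (i < nr) m[i + 1, j] else 0L,
              if (j > 1) m[i, j - 1] else 0L,
              if (j < nc) m[i, j + 1] else 0L)
      if (any(nb == 0L)) out <- rbind(out, c(i, j))
    }
    out
  }
  region <- function(m) {
    b <- boundary(m)
    nr <- nrow(m); nc <- ncol(m)
    inB <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      dmin <- min(sqrt((b[, 1] - i)^2 + (b[, 2] - j)^2))
      inB[i, j] <- dmin <= tau
    }
    inB
  }
  bg <- region(g); bt <- region(t)
  2 * sum(bg & bt) / (sum(bg) + sum(bt))
}

# Brute-force union-find single linkage at cutoff alpha (exact distances).
bruteClusterCount <- function(pos, alpha) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (d <= alpha + 1e-12) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Partition equality: do two labelings induce the same grouping?
samePartition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
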