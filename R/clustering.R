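#' Spatial clustering of the final particle configuration
#'
#' Groups particles that ended up spatially close: two particles belong to
#' the same cluster when they are linked by a chain of neighbors at Euclidean
#' distance at most `alpha` (single linkage on positions only; features play
#' no role here). `alpha` defaults to the pixel size \eqn{\Delta x}.
#'
#' For scalability the linkage is computed on positions quantized to a grid
#' of pitch `alpha/2`: particles snapping to the same grid node are at most
#' \eqn{\alpha/\sqrt 2} apart and are merged outright, and two nodes are
#' linked when their centers lie within `alpha`. This keeps the clustering
#' near-linear in N, deterministic and independent of particle order; the
#' price is a sub-pixel quantization fuzz at the linkage boundary (the
#' vignette discusses it).
#'
#' @param x a [ParticleEnsemble-class] or an N x 2 position matrix.
#' @param alpha linkage cutoff (> 0); defaults to the ensemble's pixel
#'   spacing.
#' @return A [ClusterLabeling-class]. Labels are canonical: clusters are
#'   numbered by their smallest member particle index, so the labeling is
#'   invariant under permutations of the input.
#' @export
clusterParticles <- function(x, alpha = NULL) {
  if (is(x, "ParticleEnsemble")) {
    if (is.null(alpha)) alpha <- x@spacing
    pos <- x@positions
    feat <- x@features
  } else {
    pos <- x
    feat <- rep(0, nrow(pos))
    if (is.null(alpha)) stop("'alpha' is required for a raw position matrix")
  }
  if (alpha <= 0) stop("'alpha' must be positive")
  n <- nrow(pos)

  g <- alpha / 2
  kx <- round(pos[, 1] / g)
  ky <- round(pos[, 2] / g)
  # single double key; coordinates are far below 2^25 cells in practice
  M <- 2^26
  key <- kx * M + ky
  uk <- unique(key)
  node <- match(key, uk)
  u <- length(uk)
  ukx <- round(uk / M)
  uky <- uk - ukx * M

  # node-center offsets with |offset| * g <= alpha, i.e. dx^2 + dy^2 <= 4
  offs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L),
                c(2L, 0L), c(0L, 2L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    tgt <- (ukx + offs[k, 1]) * M + (uky + offs[k, 2])
    m <- match(tgt, uk)
    hit <- which(!is.na(m))
    from <- c(from, hit); to <- c(to, m[hit])
  }

  member <- if (length(from)) {
    gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    miss <- u - igraph::vcount(gr)
    if (miss > 0) gr <- igraph::add_vertices(gr, miss)
    igraph::components(gr)$membership
  } else seq_len(u)

  raw <- member[node]
  # canonicalize: order clusters by smallest member particle index
  firstSeen <- !duplicated(raw)
  lab <- match(raw, raw[firstSeen])
  k <- max(lab)
  size <- tabulate(lab, nbins = k)
  meanFeat <- as.vector(rowsum(feat, lab)) / size
  new("ClusterLabeling", id = as.integer(lab),
      meanFeature = meanFeat, size = as.integer(size),
      alpha = as.numeric(alpha))
}

#' @describeIn clusterParticles Number of clusters in a labeling.
#' @param labeling a [ClusterLabeling-class].
#' @export
nClusters <- function(labeling) {
  stopifnot(is(labeling, "ClusterLabeling"))
  length(labeling@size)
}

#' Paint cluster means back onto the pixel grid
#'
#' Builds the multilevel mask: every pixel receives the mean gray feature of
#' the cluster its particle joined, written at the particle's original grid
#' position. The result is an image made of a small number of homogeneous
#' gray regions, ready for binarization.
#'
#' @param labeling a [ClusterLabeling-class] from [clusterParticles()].
#' @param ensemble the [ParticleEnsemble-class] that was clustered (provides
#'   the particle-to-pixel mapping and image shape).
#' @return A [GrayImage-class] of cluster means.
#' @export
buildMultilevelMask <- function(labeling, ensemble) {
  stopifnot(is(labeling, "ClusterLabeling"), is(ensemble, "ParticleEnsemble"))
  if (length(labeling@id) != nrow(ensemble@positions))
    stop("labeling does not cover the ensemble")
  vals <- matrix(NA_real_, ensemble@dim[1], ensemble@dim[2])
  vals[ensemble@pixelIndex] <- labeling@meanFeature[labeling@id]
  if (any(is.na(vals))) stop("labeling does not cover all pixels")
  new("GrayImage", values = vals, raw = NULL)
}

setMethod("show", "ClusterLabeling", function(object) {
  cat(sprintf("ClusterLabeling: %d particles in %d clusters (alpha=%.4g)\n",
              length(object@id), length(object@size), object@alpha))
})
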