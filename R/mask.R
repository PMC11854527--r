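#' Region-of-interest percentile threshold
#'
#' Computes the binarization threshold \eqn{\tilde c} as a percentile
#' (default the 10th) of the image's gray values over the ground-truth
#' foreground pixels. Quantiles use linear interpolation between order
#' statistics (R's default type 7).
#'
#' @param image a [GrayImage-class] (typically the multilevel mask).
#' @param gtMask ground-truth [BinaryMask-class] with nonempty foreground.
#' @param percentile percentile in \eqn{[0, 100]} (default 10).
#' @return The threshold \eqn{\tilde c}.
#' @export
roiPercentileThreshold <- function(image, gtMask, percentile = 10) {
  stopifnot(is(image, "GrayImage"), is(gtMask, "BinaryMask"))
  if (percentile < 0 || percentile > 100)
    stop("'percentile' must be in [0, 100]")
  if (!identical(dim(image@values), dim(gtMask@values)))
    stop("image and mask shapes differ")
  fg <- image@values[gtMask@values == 1L]
  if (length(fg) == 0L) stop("ground-truth mask has empty foreground")
  quantile(fg, percentile / 100, type = 7, names = FALSE)
}

#' Binarize a gray image at a threshold
#'
#' Pixelwise rule \eqn{1} iff \eqn{c \ge \tilde c} (closed at the threshold),
#' else 0.
#'
#' @param image a [GrayImage-class].
#' @param threshold gray cutoff \eqn{\tilde c} in \eqn{[0, 1]}.
#' @return A [BinaryMask-class] of the same shape.
#' @export
binarize <- function(image, threshold) {
  stopifnot(is(image, "GrayImage"))
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  v <- image@values
  new("BinaryMask",
      values = matrix(as.integer(v >= threshold), nrow(v), ncol(v)))
}

#' Label connected components of a binary matrix
#'
#' Connected-component labeling with selectable pixel connectivity
#' (8-neighborhood for foreground objects, 4-neighborhood for background, the
#' standard dual pair that avoids topological paradoxes).
#'
#' @param m 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 where `m == 0`).
#' @keywords internal
labelComponents <- function(m, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m == 1L)
  if (length(fg) == 0L) return(matrix(0L, nr, nc))
  node <- matrix(0L, nr, nc)
  node[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L

  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- node[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    from <- c(from, node[fg[ok]][hit]); to <- c(to, nb[hit])
  }
  lab <- if (length(from)) {
    gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    miss <- length(fg) - igraph::vcount(gr)
    if (miss > 0) gr <- igraph::add_vertices(gr, miss)
    igraph::components(gr)$membership
  } else seq_along(fg)
  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(lab)
  out
}

#' Morphological refinement of a binary mask
#'
#' Two-pass cleanup: first, foreground connected components (8-connectivity)
#' with fewer than `minSizeFg` pixels are reassigned to background; then
#' background components (4-connectivity) of the intermediate mask with fewer
#' than `minSizeBg` pixels are filled. The pass order is foreground first.
#' The operation is idempotent.
#'
#' @param mask a [BinaryMask-class].
#' @param minSizeFg,minSizeBg minimum surviving component sizes in pixels
#'   (>= 0; 0 disables a pass).
#' @return The refined [BinaryMask-class].
#' @export
morphologicalRefine <- function(mask, minSizeFg, minSizeBg) {
  stopifnot(is(mask, "BinaryMask"))
  if (minSizeFg < 0 || minSizeBg < 0) stop("minimum sizes must be >= 0")
  v <- mask@values
  if (minSizeFg > 0) {
    lab <- labelComponents(v, 8L)
    if (max(lab) > 0) {
      sz <- tabulate(lab[lab > 0L])
      v[lab > 0L & sz[pmax(lab, 1L)] < minSizeFg] <- 0L
    }
  }
  if (minSizeBg > 0) {
    lab <- labelComponents(1L - v, 4L)
    if (max(lab) > 0) {
      sz <- tabulate(lab[lab > 0L])
      v[lab > 0L & sz[pmax(lab, 1L)] < minSizeBg] <- 1L
    }
  }
  new("BinaryMask", values = v)
}

#' Segment a grayscale image with the kinetic consensus pipeline
#'
#' Full pipeline: spawn one particle per pixel on the scaled lattice, run the
#' DSMC bounded-confidence dynamics to numerical equilibrium, cluster the
#' final positions, paint cluster mean gray levels back onto the pixel grid
#' (multilevel mask), binarize at the ROI percentile threshold and apply the
#' two-pass morphological refinement. Deterministic given `seed`.
#'
#' @param image a [GrayImage-class] (or a raw gray matrix, which is first
#'   passed through [normalizeGray()]).
#' @param params a [KineticParams-class].
#' @param gtMask ground-truth [BinaryMask-class] used for the percentile
#'   threshold (calibration setting). Omit it only together with
#'   `thresholdOverride`.
#' @param alpha cluster linkage cutoff; default the pixel size \eqn{\Delta x}.
#' @param percentile ROI percentile for \eqn{\tilde c} (default 10).
#' @param minSizeFg,minSizeBg refinement thresholds; default 0.1\% of the
#'   pixel count each.
#' @param thresholdOverride absolute threshold in \eqn{[0,1]} replacing the
#'   ROI percentile rule (inference without ground truth).
#' @param seed optional integer seed for the whole pipeline.
#' @return A [SegmentationResult-class].
#' @examples
#' fx <- makeGeometricFixture("square", size = 32, blurScale = 0, seed = 1)
#' p <- kineticParams(0.5, 0.9, 0, dt = 0.5, tMax = 20)
#' res <- segment(fx$image, p, gtMask = fx$mask, seed = 7)
#' identical(maskValues(segmentationMask(res)), maskValues(fx$mask))
#' @export
segment <- function(image, params, gtMask = NULL, alpha = NULL,
                    percentile = 10, minSizeFg = NULL, minSizeBg = NULL,
                    thresholdOverride = NULL, seed = NULL) {
  if (is.matrix(image)) image <- normalizeGray(image)
  stopifnot(is(image, "GrayImage"), is(params, "KineticParams"))
  if (is.null(gtMask) && is.null(thresholdOverride))
    stop("provide 'gtMask' (percentile threshold) or 'thresholdOverride'")
  npix <- length(image@values)
  if (is.null(minSizeFg)) minSizeFg <- round(0.001 * npix)
  if (is.null(minSizeBg)) minSizeBg <- round(0.001 * npix)

  ens <- particlesFromImage(image)
  if (is.null(alpha)) alpha <- ens@spacing
  sim <- runSimulation(ens, params, seed = seed)
  labeling <- clusterParticles(sim@ensemble, alpha = alpha)
  multilevel <- buildMultilevelMask(labeling, sim@ensemble)
  thr <- if (!is.null(thresholdOverride)) thresholdOverride else
    roiPercentileThreshold(multilevel, gtMask, percentile)
  mask <- morphologicalRefine(binarize(multilevel, thr), minSizeFg, minSizeBg)
  new("SegmentationResult", mask = mask, multilevel = multilevel,
      threshold = thr, labeling = labeling, simulation = sim,
      params = params)
}

#' @describeIn segment Accessor for the final refined mask.
#' @param x a [SegmentationResult-class].
#' @export
segmentationMask <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@mask
}

#' @describeIn segment Accessor for the multilevel (cluster-mean) mask.
#' @export
multilevelMask <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@multilevel
}

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@mask@values)
  cat(sprintf(paste0("SegmentationResult %d x %d: %d foreground pixels, ",
                     "%d clusters, threshold %.4g\n"),
              d[1], d[2], sum(object@mask@values),
              length(object@labeling@size), object@threshold))
})
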