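#' @include kinseg-package.R
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GrayImage: a normalized grayscale image
#'
#' Container for a 2D grayscale image whose per-pixel feature values live in
#' \eqn{[0,1]} (0 = black, 1 = white). The original gray levels, when known,
#' are kept alongside in the \code{raw} slot. Use [normalizeGray()] to build a
#' `GrayImage` from an arbitrary gray-level matrix.
#'
#' @slot values numeric matrix of normalized gray features in \eqn{[0,1]}.
#' @slot raw original gray-level matrix, or `NULL` when not available.
#' @seealso [normalizeGray()], [particlesFromImage()]
#' @export
setClass("GrayImage",
  representation(values = "matrix", raw = "matrixOrNULL"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L) return("image must be at least 2x2 pixels")
    if (any(!is.finite(v))) return("'values' must be finite")
    if (any(v < 0) || any(v > 1)) return("'values' must lie in [0, 1]")
    if (!is.null(object@raw) && !identical(dim(object@raw), dim(v)))
      return("'raw' must have the same dimensions as 'values'")
    TRUE
  }
)

#' PixelGrid: scaled initial particle positions of an image
#'
#' Regular lattice mapping every pixel of an `height x width` image into the
#' square \eqn{[-1,1]^2}. Each axis is mapped affinely onto \eqn{[-1,1]}; the
#' scalar `spacing` is the lattice pitch \eqn{2/(\max(h,w)-1)}, i.e. the
#' distance between adjacent pixel positions along the longer axis.
#'
#' @slot positions N x 2 matrix of (x, y) coordinates, one row per pixel in
#'   column-major pixel order (pixel (i, j) is row `(j-1)*height + i`).
#' @slot dim integer vector `c(height, width)`.
#' @slot spacing lattice pitch \eqn{\Delta x}.
#' @export
setClass("PixelGrid",
  representation(positions = "matrix", dim = "integer", spacing = "numeric"),
  validity = function(object) {
    if (ncol(object@positions) != 2L) return("'positions' must have 2 columns")
    if (length(object@dim) != 2L || any(object@dim < 2L))
      return("'dim' must be two integers >= 2")
    if (nrow(object@positions) != prod(object@dim))
      return("'positions' must have height*width rows")
    if (object@spacing <= 0) return("'spacing' must be positive")
    TRUE
  }
)

#' ParticleEnsemble: the interacting-pixel particle system
#'
#' State of the particle system evolved by the DSMC scheme: particle positions
#' in the plane and their static gray features. Features never change during a
#' simulation; `pixelIndex` maps each particle back to the pixel (column-major
#' linear index) it was spawned from, so cluster structure can be painted back
#' onto the original pixel grid.
#'
#' @slot positions N x 2 numeric matrix of particle coordinates.
#' @slot features numeric vector of N static gray features in \eqn{[0,1]}.
#' @slot pixelIndex integer vector mapping particles to pixel linear indices.
#' @slot dim integer `c(height, width)` of the source image.
#' @slot spacing lattice pitch of the initial pixel positions.
#' @seealso [particlesFromImage()], [dsmcStep()], [runSimulation()]
#' @export
setClass("ParticleEnsemble",
  representation(positions = "matrix", features = "numeric",
                 pixelIndex = "integer", dim = "integer", spacing = "numeric"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (ncol(object@positions) != 2L) return("'positions' must have 2 columns")
    if (length(object@features) != n)
      return("'features' must have one entry per particle")
    if (any(!is.finite(object@features)) ||
        any(object@features < 0) || any(object@features > 1))
      return("'features' must lie in [0, 1]")
    if (length(object@pixelIndex) != n)
      return("'pixelIndex' must have one entry per particle")
    TRUE
  }
)

#' KineticParams: parameters of the bounded-confidence kinetic model
#'
#' Bundles the three model parameters (spatial confidence bound `delta1`,
#' feature confidence bound `delta2`, diffusion strength `sigma2`) together
#' with the numerical settings of the DSMC scheme: time step `dt` (the binary
#' interaction strength \eqn{\epsilon}), diffusion-function selector, final
#' time `tMax`, equilibrium stopping tolerance `stopDelta` on the density
#' variation index, and the histogram geometry used for that index.
#'
#' @slot delta1 spatial confidence bound (scaled-position units, >= 0).
#' @slot delta2 feature confidence bound (gray units, >= 0).
#' @slot sigma2 diffusion strength (>= 0).
#' @slot dt time step \eqn{\epsilon}, in (0, 1].
#' @slot diffusion one of `"d1"`, `"d2"`, `"d3"`, `"d4"`, `"custom"`.
#' @slot diffusionFun user diffusion function when `diffusion == "custom"`.
#' @slot tMax final time horizon.
#' @slot stopDelta stopping tolerance on the density variation (> 0).
#' @slot histBins integer `c(nx, ny, nc)` bins over \eqn{[-1,1]^2 \times [0,1]}.
#' @slot histEvery recompute the density histogram every this many steps.
#' @slot clampDomain clamp positions to \eqn{[-1,1]^2} after each step
#'   (default `FALSE`: free space, no boundary condition).
#' @seealso [kineticParams()], [runSimulation()]
#' @export
setClass("KineticParams",
  representation(delta1 = "numeric", delta2 = "numeric", sigma2 = "numeric",
                 dt = "numeric", diffusion = "character",
                 diffusionFun = "functionOrNULL",
                 tMax = "numeric", stopDelta = "numeric",
                 histBins = "integer", histEvery = "integer",
                 clampDomain = "logical"),
  validity = function(object) {
    if (object@delta1 < 0 || object@delta2 < 0 || object@sigma2 < 0)
      return("'delta1', 'delta2' and 'sigma2' must be nonnegative")
    if (object@dt <= 0 || object@dt > 1) return("'dt' must be in (0, 1]")
    if (!object@diffusion %in% c("d1", "d2", "d3", "d4", "custom"))
      return("'diffusion' must be one of d1, d2, d3, d4, custom")
    if (object@diffusion == "custom" && is.null(object@diffusionFun))
      return("'diffusionFun' is required when diffusion == 'custom'")
    if (object@tMax <= 0) return("'tMax' must be positive")
    if (object@stopDelta <= 0) return("'stopDelta' must be positive")
    if (length(object@histBins) != 3L || any(object@histBins < 1L))
      return("'histBins' must be three positive integers")
    if (object@histEvery < 1L) return("'histEvery' must be >= 1")
    TRUE
  }
)

#' DensityHistogram: discrete phase-space density
#'
#' Normalized histogram of the particle ensemble over the phase space
#' \eqn{[-1,1]^2 \times [0,1]} (position times gray feature). Particles that
#' have diffused outside the spatial domain are excluded and the remaining
#' mass is renormalized to 1, so the histogram always describes the in-domain
#' density shape.
#'
#' @slot prob 3D array of bin probabilities (sums to 1).
#' @slot bins integer `c(nx, ny, nc)`.
#' @slot nInside number of particles inside the spatial domain.
#' @seealso [densityHistogram()], [densityVariation()]
#' @export
setClass("DensityHistogram",
  representation(prob = "array", bins = "integer", nInside = "integer"),
  validity = function(object) {
    if (length(object@bins) != 3L) return("'bins' must have length 3")
    if (!identical(dim(object@prob), as.integer(object@bins)))
      return("'prob' dimensions must match 'bins'")
    if (any(object@prob < 0)) return("'prob' must be nonnegative")
    if (abs(sum(object@prob) - 1) > 1e-8) return("'prob' must sum to 1")
    TRUE
  }
)

#' SimulationResult: output of a DSMC run
#'
#' @slot ensemble final [ParticleEnsemble-class] state.
#' @slot trace data.frame with columns `step`, `time`, `variation`: the
#'   density-variation index recorded at each histogram checkpoint.
#' @slot converged `TRUE` when the variation fell below the stopping tolerance
#'   before the time horizon.
#' @slot finalTime simulated time at which the run ended.
#' @export
setClass("SimulationResult",
  representation(ensemble = "ParticleEnsemble", trace = "data.frame",
                 converged = "logical", finalTime = "numeric"))

#' BinaryMask: a 0/1 segmentation mask
#'
#' @slot values integer matrix with entries in \{0, 1\}; same shape as the
#'   image it segments.
#' @seealso [binarize()], [readMask()], [writeMask()]
#' @export
setClass("BinaryMask",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!all(v %in% c(0L, 1L))) return("mask values must be 0 or 1")
    TRUE
  }
)

#' ClusterLabeling: spatial clusters of the final particle configuration
#'
#' @slot id integer vector assigning every particle to exactly one cluster
#'   (labels are canonical: cluster 1 contains the smallest particle index).
#' @slot meanFeature per-cluster mean gray feature, in \eqn{[0,1]}.
#' @slot size per-cluster particle count.
#' @slot alpha linkage cutoff used (position units).
#' @seealso [clusterParticles()], [buildMultilevelMask()]
#' @export
setClass("ClusterLabeling",
  representation(id = "integer", meanFeature = "numeric", size = "integer",
                 alpha = "numeric"),
  validity = function(object) {
    k <- length(object@meanFeature)
    if (length(object@size) != k) return("'size' and 'meanFeature' lengths differ")
    if (any(object@id < 1L) || any(object@id > k)) return("cluster ids out of range")
    if (any(object@meanFeature < 0) || any(object@meanFeature > 1))
      return("cluster mean features must lie in [0, 1]")
    TRUE
  }
)

#' ConfusionCounts: pixel-level confusion counts of two binary masks
#'
#' @slot tp,fp,fn,tn nonnegative pixel counts (true/false positives/negatives
#'   of the predicted mask against the ground truth).
#' @seealso [confusionCounts()], [fBeta()], [precisionSensitivity()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"),
  validity = function(object) {
    if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
      return("counts must be nonnegative")
    TRUE
  }
)

#' MetricReport: evaluation of a predicted mask against a ground truth
#'
#' @slot counts [ConfusionCounts-class] of the pair of masks.
#' @slot metrics named numeric vector of metric values.
#' @slot loss `1 - value` of the metric selected in `config`.
#' @slot config named list echoing the metric configuration.
#' @seealso [evaluateMask()], [writeMetricReport()]
#' @export
setClass("MetricReport",
  representation(counts = "ConfusionCounts", metrics = "numeric",
                 loss = "numeric", config = "list"))

#' SearchSpace: sampling distributions for random-search calibration
#'
#' The three model parameters are drawn independently per trial:
#' \eqn{\Delta_1 \sim U(\Delta x, 0.7)} (the lower bound defaults to the pixel
#' spacing of the image being calibrated), \eqn{\Delta_2 \sim U(0.05, 0.3)}
#' and \eqn{\sigma^2 = e^u, u \sim U(-5, 1)} (log-uniform on
#' \eqn{[e^{-5}, e]}).
#'
#' @slot delta1Range,delta2Range numeric `c(low, high)` uniform bounds;
#'   `delta1Range[1]` may be `NA` to mean "use the image pixel spacing".
#' @slot logSigma2Range numeric `c(low, high)` bounds of the log of
#'   \eqn{\sigma^2}.
#' @slot nIter number of random-search iterations.
#' @seealso [searchSpace()], [sampleParams()], [calibrate()]
#' @export
setClass("SearchSpace",
  representation(delta1Range = "numeric", delta2Range = "numeric",
                 logSigma2Range = "numeric", nIter = "integer"),
  validity = function(object) {
    chk <- function(r, nm, naOK = FALSE) {
      if (length(r) != 2L) return(sprintf("'%s' must have length 2", nm))
      if (!naOK && any(is.na(r))) return(sprintf("'%s' must be finite", nm))
      if (!any(is.na(r)) && r[1] >= r[2])
        return(sprintf("'%s' low must be < high", nm))
      TRUE
    }
    for (res in list(chk(object@delta1Range, "delta1Range", naOK = TRUE),
                     chk(object@delta2Range, "delta2Range"),
                     chk(object@logSigma2Range, "logSigma2Range")))
      if (!isTRUE(res)) return(res)
    if (object@nIter < 1L) return("'nIter' must be >= 1")
    TRUE
  }
)

#' CalibrationResult: outcome of a random-search calibration
#'
#' @slot best [KineticParams-class] of the best (lowest-loss) trial.
#' @slot bestLoss lowest loss found.
#' @slot trials full trial ledger: one row per iteration with the sampled
#'   parameters, the per-trial simulation seed, and the achieved loss.
#' @slot metric named list echoing the metric configuration optimized.
#' @seealso [calibrate()]
#' @export
setClass("CalibrationResult",
  representation(best = "KineticParams", bestLoss = "numeric",
                 trials = "data.frame", metric = "list"),
  validity = function(object) {
    if (nrow(object@trials) > 0 &&
        abs(object@bestLoss - min(object@trials$loss)) > 1e-12)
      return("'bestLoss' must equal the minimum loss in 'trials'")
    TRUE
  }
)

#' SegmentationResult: full output of the segmentation pipeline
#'
#' @slot mask final refined [BinaryMask-class].
#' @slot multilevel multilevel mask ([GrayImage-class]): every pixel carries
#'   the mean gray feature of the cluster its particle joined.
#' @slot threshold binarization threshold \eqn{\tilde c} used.
#' @slot labeling [ClusterLabeling-class] of the final particle configuration.
#' @slot simulation [SimulationResult-class] of the underlying DSMC run.
#' @slot params [KineticParams-class] used.
#' @export
setClass("SegmentationResult",
  representation(mask = "BinaryMask", multilevel = "GrayImage",
                 threshold = "numeric", labeling = "ClusterLabeling",
                 simulation = "SimulationResult", params = "KineticParams"))
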