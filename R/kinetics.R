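#' Bounded-confidence interaction kernel
#'
#' Two particles interact iff they are close both in space and in gray level:
#' \eqn{P_{\Delta_1,\Delta_2} = \chi(|x_a - x_b| \le \Delta_1)\,
#' \chi(|c_a - c_b| \le \Delta_2)}. Both inequalities are closed, and the
#' kernel is symmetric in its two particles. Vectorized over particle pairs.
#'
#' @param xa,xb positions: numeric length-2 vectors or n x 2 matrices.
#' @param ca,cb gray features in \eqn{[0,1]}.
#' @param delta1 spatial confidence bound (>= 0).
#' @param delta2 feature confidence bound (>= 0).
#' @return 0/1 numeric vector.
#' @export
interactionKernel <- function(xa, xb, ca, cb, delta1, delta2) {
  if (is.null(dim(xa))) xa <- matrix(xa, ncol = 2)
  if (is.null(dim(xb))) xb <- matrix(xb, ncol = 2)
  stopifnot(all(is.finite(xa)), all(is.finite(xb)),
            all(is.finite(ca)), all(is.finite(cb)),
            delta1 >= 0, delta2 >= 0)
  d2 <- (xa[, 1] - xb[, 1])^2 + (xa[, 2] - xb[, 2])^2
  as.numeric(d2 <= delta1^2 & abs(ca - cb) <= delta2)
}

#' Feature-dependent diffusion functions
#'
#' The diffusion coefficient \eqn{D(c)} modulates the noise felt by a particle
#' according to its gray level: aleatoric acquisition noise is expected in the
#' mid-gray range, so all built-in choices vanish at the feature boundaries,
#' \eqn{D(0) = D(1) = 0}, and peak at \eqn{c = 1/2}:
#' \deqn{D_1(c) = c(1-c), \quad D_2(c) = 4c^2(1-c)^2,}
#' \deqn{D_3(c) = c^2 \ (c \le 1/2);\ c^2(1-c) \ (c > 1/2), \quad
#'       D_4(c) = 64 c^4 (1-c)^4.}
#'
#' @param c gray feature values in \eqn{[0,1]} (error otherwise).
#' @param diffusion one of `"d1"`, `"d2"`, `"d3"`, `"d4"`, or `"custom"`
#'   together with `fun`.
#' @param fun custom diffusion function of `c`, used when
#'   `diffusion == "custom"`.
#' @return Nonnegative numeric vector of the same length as `c`.
#' @examples
#' diffusionValue(0.5, "d1")  # 0.25
#' diffusionValue(0.6, "d3")  # 0.144
#' @export
diffusionValue <- function(c, diffusion = c("d1", "d2", "d3", "d4", "custom"),
                           fun = NULL) {
  diffusion <- match.arg(diffusion)
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stop("features 'c' must lie in [0, 1]")
  out <- switch(diffusion,
    d1 = c * (1 - c),
    d2 = 4 * c^2 * (1 - c)^2,
    d3 = ifelse(c <= 0.5, c^2, c^2 * (1 - c)),
    d4 = 64 * c^4 * (1 - c)^4,
    custom = {
      if (is.null(fun)) stop("'fun' is required for custom diffusion")
      fun(c)
    })
  if (any(out < 0)) stop("diffusion values must be nonnegative")
  out
}

#' Stochastic rounding
#'
#' Unbiased randomized rounding of nonnegative reals:
#' \eqn{S_{round}(x) = \lfloor x \rfloor + 1} with probability
#' \eqn{x - \lfloor x \rfloor}, else \eqn{\lfloor x \rfloor}. Used to pick the
#' number of interaction pairs \eqn{n_p = S_{round}(N/2)} per DSMC step so the
#' expected pair count is exact even for odd N.
#'
#' @param x nonnegative numeric vector.
#' @return Integer vector, elementwise in \eqn{\{\lfloor x\rfloor,
#'   \lceil x\rceil\}}, unbiased in expectation.
#' @export
stochasticRound <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("'x' must be nonnegative")
  f <- floor(x)
  as.integer(f + (runif(length(x)) < (x - f)))
}

#' Construct kinetic model parameters
#'
#' Convenience constructor for [KineticParams-class]; see that class for the
#' meaning and constraints of every field.
#'
#' @param delta1,delta2 spatial and feature confidence bounds.
#' @param sigma2 diffusion strength.
#' @param dt time step \eqn{\epsilon} in (0, 1].
#' @param diffusion diffusion-function id (`"d1"` ... `"d4"` or `"custom"`).
#' @param diffusionFun function of `c`, required for `"custom"`.
#' @param tMax time horizon.
#' @param stopDelta stopping tolerance on the density-variation index.
#' @param histBins histogram bins `c(nx, ny, nc)` over
#'   \eqn{[-1,1]^2 \times [0,1]}.
#' @param histEvery steps between histogram checkpoints.
#' @param clampDomain clamp positions to \eqn{[-1,1]^2} (default free space).
#' @return A [KineticParams-class].
#' @export
kineticParams <- function(delta1, delta2, sigma2, dt = 0.1,
                          diffusion = "d1", diffusionFun = NULL,
                          tMax = 200, stopDelta = 0.005,
                          histBins = c(50L, 50L, 10L), histEvery = 10L,
                          clampDomain = FALSE) {
  new("KineticParams", delta1 = as.numeric(delta1),
      delta2 = as.numeric(delta2), sigma2 = as.numeric(sigma2),
      dt = as.numeric(dt), diffusion = diffusion,
      diffusionFun = diffusionFun, tMax = as.numeric(tMax),
      stopDelta = as.numeric(stopDelta), histBins = as.integer(histBins),
      histEvery = as.integer(histEvery), clampDomain = clampDomain)
}

#' One DSMC (Nanbu-Babovsky) step of the binary interaction scheme
#'
#' Draws \eqn{n_p = S_{round}(N/2)} disjoint particle pairs uniformly at
#' random; each paired particle moves by
#' \deqn{\Delta x_i = \epsilon P_{\Delta_1,\Delta_2}(x_i, x_j, c_i, c_j)
#'       (x_j - x_i) + \sqrt{2\sigma^2 D(c_i)}\,\eta_i,}
#' with an independent centered 2D Gaussian \eqn{\eta} per particle whose
#' per-component variance is \eqn{\epsilon} (the Euler-Maruyama reading of
#' the noise term). Features are static; unpaired particles (the leftover one
#' when N is odd) do not move.
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param params a [KineticParams-class].
#' @param noiseCoef optional precomputed per-particle noise amplitude
#'   \eqn{\sqrt{2\sigma^2 D(c_i)}}; since features are static, a full run can
#'   compute it once ([runSimulation()] does).
#' @return The updated [ParticleEnsemble-class].
#' @seealso [runSimulation()] for the full loop with stopping criterion.
#' @export
dsmcStep <- function(ensemble, params, noiseCoef = NULL) {
  pos <- ensemble@positions
  feat <- ensemble@features
  n <- nrow(pos)
  # for odd N the leftover particle after floor(N/2) pairs sits out this step
  np <- min(stochasticRound(n / 2), n %/% 2L)
  if (np == 0L) return(ensemble)

  idx <- sample.int(n, 2L * np)
  i <- idx[seq_len(np)]
  j <- idx[np + seq_len(np)]

  dvec <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  p <- as.numeric(dvec[, 1]^2 + dvec[, 2]^2 <= params@delta1^2 &
                  abs(feat[i] - feat[j]) <= params@delta2)
  drift <- (params@dt * p) * dvec

  di <- drift
  dj <- -drift
  if (params@sigma2 > 0) {
    if (is.null(noiseCoef))
      noiseCoef <- sqrt(2 * params@sigma2 *
                        diffusionValue(feat, params@diffusion,
                                       params@diffusionFun))
    sdq <- sqrt(params@dt)
    di <- di + noiseCoef[i] * matrix(rnorm(2L * np, sd = sdq), np, 2L)
    dj <- dj + noiseCoef[j] * matrix(rnorm(2L * np, sd = sdq), np, 2L)
  }
  pos[i, ] <- pos[i, , drop = FALSE] + di
  pos[j, ] <- pos[j, , drop = FALSE] + dj
  if (params@clampDomain) pos[] <- pmin(pmax(pos, -1), 1)

  ensemble@positions <- pos
  ensemble
}

#' Phase-space density histogram of an ensemble
#'
#' Bins the particles over \eqn{[-1,1]^2 \times [0,1]} (x, y, feature) and
#' normalizes to total mass 1. Particles that have diffused outside the
#' spatial domain (possible under free-space boundary handling) are excluded
#' before normalization, so the histogram tracks the shape of the in-domain
#' density.
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param bins integer `c(nx, ny, nc)`.
#' @return A [DensityHistogram-class].
#' @export
densityHistogram <- function(ensemble, bins = c(50L, 50L, 10L)) {
  bins <- as.integer(bins)
  pos <- ensemble@positions
  feat <- ensemble@features
  inside <- pos[, 1] >= -1 & pos[, 1] <= 1 & pos[, 2] >= -1 & pos[, 2] <= 1
  if (!any(inside))
    stop("no particle inside the spatial domain [-1,1]^2")
  x <- pos[inside, 1]; y <- pos[inside, 2]; cc <- feat[inside]
  ix <- pmin(pmax(floor((x + 1) / 2 * bins[1]) + 1L, 1L), bins[1])
  iy <- pmin(pmax(floor((y + 1) / 2 * bins[2]) + 1L, 1L), bins[2])
  ic <- pmin(pmax(floor(cc * bins[3]) + 1L, 1L), bins[3])
  lin <- (ic - 1L) * bins[1] * bins[2] + (iy - 1L) * bins[1] + ix
  counts <- tabulate(lin, nbins = prod(bins))
  new("DensityHistogram",
      prob = array(counts / sum(counts), dim = bins),
      bins = bins, nInside = sum(inside))
}

#' Variation index between two density histograms
#'
#' Discrete L1 distance \eqn{\sum_b |p^{(n+1)}_b - p^{(n)}_b|} between two
#' successive normalized phase-space histograms, the discretization of the
#' integral \eqn{\int |f_{n+1} - f_n|\,dx\,dc}. It is 0 for identical
#' densities and at most 2 (disjoint supports); its decay toward 0 signals
#' that the particle system has reached a numerical steady state.
#'
#' @param histPrev,histNext [DensityHistogram-class] objects on identical bin
#'   geometry.
#' @return Nonnegative scalar in \eqn{[0, 2]}.
#' @export
densityVariation <- function(histPrev, histNext) {
  stopifnot(is(histPrev, "DensityHistogram"), is(histNext, "DensityHistogram"))
  if (!identical(histPrev@bins, histNext@bins))
    stop("histograms have mismatched bin geometry")
  sum(abs(histNext@prob - histPrev@prob))
}

#' Run the DSMC simulation to (numerical) equilibrium
#'
#' Iterates [dsmcStep()] for \eqn{N_t = T_{max}/\epsilon} steps, recomputing
#' the phase-space histogram every `histEvery` steps and recording the
#' variation index between successive checkpoints. The loop halts early once
#' the variation drops below `stopDelta`, at which point the reconstructed
#' density is taken as an approximation of the steady state.
#'
#' @param ensemble initial [ParticleEnsemble-class].
#' @param params a [KineticParams-class].
#' @param seed optional integer seed; when given, the entire trajectory is
#'   reproducible bit-for-bit.
#' @return A [SimulationResult-class] holding the final ensemble, the
#'   variation trace, and whether the stopping criterion fired.
#' @export
runSimulation <- function(ensemble, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- floor(params@tMax / params@dt + 1e-9)
  if (abs(nt * params@dt - params@tMax) > 1e-9 * max(1, params@tMax))
    warning("'tMax' is not a multiple of 'dt'; running ", nt, " steps")

  noiseCoef <- if (params@sigma2 > 0)
    sqrt(2 * params@sigma2 *
         diffusionValue(ensemble@features, params@diffusion,
                        params@diffusionFun)) else NULL
  hPrev <- densityHistogram(ensemble, params@histBins)
  steps <- numeric(0); vars <- numeric(0)
  converged <- FALSE
  t <- 0L
  while (t < nt) {
    t <- t + 1L
    ensemble <- dsmcStep(ensemble, params, noiseCoef)
    if (t %% params@histEvery == 0L || t == nt) {
      hNext <- densityHistogram(ensemble, params@histBins)
      v <- densityVariation(hPrev, hNext)
      steps <- c(steps, t); vars <- c(vars, v)
      hPrev <- hNext
      if (v < params@stopDelta) { converged <- TRUE; break }
    }
  }
  new("SimulationResult", ensemble = ensemble,
      trace = data.frame(step = steps, time = steps * params@dt,
                         variation = vars),
      converged = converged, finalTime = t * params@dt)
}

#' @describeIn runSimulation Accessor for the variation trace.
#' @param x a [SimulationResult-class].
#' @export
variationTrace <- function(x) {
  stopifnot(is(x, "SimulationResult"))
  x@trace
}

#' @describeIn runSimulation Accessor for the final ensemble.
#' @export
finalEnsemble <- function(x) {
  stopifnot(is(x, "SimulationResult"))
  x@ensemble
}

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(paste0("KineticParams: delta1=%.4g delta2=%.4g sigma2=%.4g ",
                     "dt=%.3g diffusion=%s tMax=%g stopDelta=%g\n"),
              object@delta1, object@delta2, object@sigma2, object@dt,
              object@diffusion, object@tMax, object@stopDelta))
})

setMethod("show", "SimulationResult", function(object) {
  nv <- nrow(object@trace)
  cat(sprintf("SimulationResult: %s at t=%.4g (last variation %s)\n",
              if (object@converged) "reached steady state" else "time horizon",
              object@finalTime,
              if (nv) signif(object@trace$variation[nv], 3) else "NA"))
})
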