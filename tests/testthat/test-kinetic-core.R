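test_that("interaction kernel gates on both bounds with closed inequalities", {
  expect_equal(interactionKernel(c(0, 0), c(0, 0), 0.5, 0.5, 0, 0), 1)
  expect_equal(interactionKernel(c(0, 0), c(0.5, 0), 0.2, 0.2, 0.3, 1), 0)
  # boundary cases: distances exactly at the bounds still interact
  expect_equal(interactionKernel(c(0, 0), c(0.3, 0), 0.1, 0.3, 0.3, 0.2), 1)
  expect_equal(interactionKernel(c(0, 0), c(0, 0.31), 0, 0, 0.3, 0.2), 0)

  # pairwise symmetry over random inputs
  set.seed(1)
  for (k in 1:50) {
    xa <- runif(2, -1, 1); xb <- runif(2, -1, 1)
    ca <- runif(1); cb <- runif(1)
    d1 <- runif(1, 0, 1.5); d2 <- runif(1, 0, 0.5)
    expect_identical(interactionKernel(xa, xb, ca, cb, d1, d2),
                     interactionKernel(xb, xa, cb, ca, d1, d2))
  }
})

test_that("diffusion functions vanish at the feature boundaries and match formulas", {
  for (d in c("d1", "d2", "d3", "d4")) {
    expect_equal(diffusionValue(0, d), 0)
    expect_equal(diffusionValue(1, d), 0)
  }
  expect_equal(diffusionValue(0.5, "d1"), 0.25)
  expect_equal(diffusionValue(0.5, "d2"), 0.25)
  expect_equal(diffusionValue(0.5, "d4"), 0.25)
  # piecewise form of D3 on both sides of 1/2
  expect_equal(diffusionValue(0.4, "d3"), 0.16)
  expect_equal(diffusionValue(0.6, "d3"), 0.144)
  expect_error(diffusionValue(1.2, "d1"), "\\[0, 1\\]")
  expect_error(diffusionValue(-0.1, "d3"), "\\[0, 1\\]")
  # custom diffusion is evaluated as given
  expect_equal(diffusionValue(0.3, "custom", fun = function(c) 2 * c), 0.6)
})

test_that("stochastic rounding is exact on integers and unbiased in expectation", {
  set.seed(7)
  expect_identical(stochasticRound(rep(3, 100)), rep(3L, 100))
  draws <- stochasticRound(rep(2.7, 1e5))
  expect_true(all(draws %in% c(2L, 3L)))
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(mean(draws) - 2.7), 3 * se)
  expect_error(stochasticRound(-1), "nonnegative")
})

test_that("a DSMC step moves nothing without interactions or noise", {
  ens <- latticeEnsemble(5, 5)
  p <- kineticParams(0, 1, 0, dt = 0.5)
  set.seed(2)
  out <- dsmcStep(ens, p)
  expect_identical(out@positions, ens@positions)
})

test_that("an interacting pair contracts to the midpoint at eps = 1/2 and swaps at eps = 1", {
  pos <- rbind(c(0, 0), c(1, 0))
  ens <- makeEnsemble(pos, c(0.5, 0.5))
  set.seed(4)
  half <- dsmcStep(ens, kineticParams(2, 1, 0, dt = 0.5))
  expect_equal(half@positions, rbind(c(0.5, 0), c(0.5, 0)))
  set.seed(4)
  swap <- dsmcStep(ens, kineticParams(2, 1, 0, dt = 1))
  expect_setequal(swap@positions[, 1], c(0, 1))
  expect_equal(sort(swap@positions[, 1]), c(0, 1))
})

test_that("noise-free steps conserve the mean position exactly", {
  set.seed(11)
  ens <- makeEnsemble(matrix(runif(400, -1, 1), 200, 2), runif(200))
  p <- kineticParams(0.5, 0.4, 0, dt = 0.3)
  m0 <- colMeans(ens@positions)
  for (k in 1:20) {
    ens <- dsmcStep(ens, p)
    expect_equal(colMeans(ens@positions), m0, tolerance = 1e-12)
  }
})

test_that("features are bit-identical through a noisy simulation", {
  set.seed(12)
  feat <- runif(100)
  ens <- makeEnsemble(matrix(runif(200, -1, 1), 100, 2), feat)
  p <- kineticParams(0.5, 0.3, 0.8, dt = 0.1, tMax = 5, histEvery = 50L)
  sim <- runSimulation(ens, p, seed = 13)
  expect_identical(finalEnsemble(sim)@features, feat)
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  ens <- latticeEnsemble(8, 8, feat = 0.4)
  p <- kineticParams(0.6, 0.5, 0.3, dt = 0.1, tMax = 3)
  a <- runSimulation(ens, p, seed = 99)
  b <- runSimulation(ens, p, seed = 99)
  expect_identical(finalEnsemble(a)@positions, finalEnsemble(b)@positions)
  expect_identical(variationTrace(a), variationTrace(b))
  c <- runSimulation(ens, p, seed = 100)
  expect_false(identical(finalEnsemble(a)@positions,
                         finalEnsemble(c)@positions))
})

test_that("density variation is an L1 distance with the expected extremes", {
  bins <- c(10L, 10L, 4L)
  ens <- makeEnsemble(matrix(runif(60, -1, 1), 30, 2), runif(30))
  h <- densityHistogram(ens, bins)
  expect_equal(sum(h@prob), 1)
  expect_equal(densityVariation(h, h), 0)

  # disjoint unit-mass histograms are at distance 2
  left <- makeEnsemble(matrix(c(rep(-0.9, 10), rep(-0.9, 10)), 10, 2), rep(0.1, 10))
  right <- makeEnsemble(matrix(c(rep(0.9, 10), rep(0.9, 10)), 10, 2), rep(0.9, 10))
  expect_equal(densityVariation(densityHistogram(left, bins),
                                densityHistogram(right, bins)), 2)

  # moving a single particle one bin shifts 2/N of mass
  n <- 25
  pos <- matrix(runif(2 * n, 0.01, 0.19), n, 2)   # all inside one bin
  moved <- pos; moved[1, 1] <- 0.3                # into the adjacent bin
  hv <- densityVariation(
    densityHistogram(makeEnsemble(pos, rep(0.5, n)), bins),
    densityHistogram(makeEnsemble(moved, rep(0.5, n)), bins))
  expect_equal(hv, 2 / n)

  expect_error(densityVariation(h, densityHistogram(ens, c(5L, 5L, 2L))),
               "mismatched")
})

test_that("full-confidence noise-free dynamics collapse to the mean (ODE oracle)", {
  set.seed(3)
  n <- 40
  pos0 <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  ens <- makeEnsemble(pos0, rep(0.5, n))
  p <- kineticParams(3, 1, 0, dt = 0.5, tMax = 60)
  sim <- runSimulation(ens, p, seed = 9)
  fin <- finalEnsemble(sim)@positions

  # Euler integration of the mean-field consensus ODE dx/dt = mean - x
  x <- pos0
  for (k in 1:1200)
    x <- x + 0.05 * (matrix(colMeans(x), n, 2, byrow = TRUE) - x)

  spread <- max(abs(sweep(fin, 2, colMeans(fin))))
  expect_lt(spread, 0.01)
  expect_equal(colMeans(fin), colMeans(x), tolerance = 1e-9)
})

test_that("an already-collapsed noise-free state is a fixed point", {
  pos <- matrix(0.2, 30, 2)
  ens <- makeEnsemble(pos, rep(0.5, 30))
  p <- kineticParams(1, 1, 0, dt = 0.5, tMax = 50)
  sim <- runSimulation(ens, p, seed = 1)
  expect_true(sim@converged)
  expect_equal(variationTrace(sim)$variation[1], 0)
  expect_identical(finalEnsemble(sim)@positions, pos)
})

test_that("cluster count is nonincreasing as the spatial bound grows", {
  for (sd in c(5, 8, 13)) {
    counts <- vapply(c(0.3, 0.6, 1.0, 2.9), function(d1) {
      p <- kineticParams(d1, 1, 0, dt = 0.2, tMax = 400, stopDelta = 1e-9)
      sim <- runSimulation(latticeEnsemble(8, 8), p, seed = sd)
      nClusters(clusterParticles(finalEnsemble(sim)@positions, alpha = 0.05))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a horizon that is not a multiple of the step warns and truncates", {
  ens <- latticeEnsemble(4, 4)
  p <- kineticParams(0.5, 1, 0, dt = 0.3, tMax = 1, stopDelta = 1e-12,
                     histEvery = 100L)
  expect_warning(sim <- runSimulation(ens, p, seed = 1), "not a multiple")
  expect_equal(sim@finalTime, 0.9)
})
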