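test_that("spatial clustering groups by proximity with canonical labels", {
  # all coincident -> one cluster
  lab <- clusterParticles(matrix(0.3, 20, 2), alpha = 0.05)
  expect_equal(nClusters(lab), 1)

  # two tight groups far apart -> two clusters
  a <- 0.02
  g1 <- matrix(runif(20, 0, 0.1 * a), 10, 2)
  g2 <- matrix(runif(20, 0, 0.1 * a) + 10 * a, 10, 2)
  lab2 <- clusterParticles(rbind(g1, g2), alpha = a)
  expect_equal(nClusters(lab2), 2)
  expect_equal(lab2@id, rep(c(1L, 2L), each = 10))
  expect_equal(lab2@size, c(10L, 10L))

  # chain at spacing exactly alpha stays one cluster (union-find oracle)
  chain <- cbind(seq(0, 9) * a, 0)
  expect_equal(nClusters(clusterParticles(chain, alpha = a)), 1)
  expect_equal(bruteClusterCount(chain, a), 1)

  # breaking one link splits the chain, as in the oracle
  gap <- chain; gap[6:10, 1] <- gap[6:10, 1] + 2 * a
  expect_equal(nClusters(clusterParticles(gap, alpha = a)),
               bruteClusterCount(gap, a))
})

test_that("clustering agrees with the union-find oracle on random blob sets", {
  set.seed(21)
  a <- 0.05
  for (k in 1:10) {
    nb <- sample(2:5, 1)
    centers <- matrix(runif(2 * nb, -0.8, 0.8), nb, 2)
    # keep blobs well separated relative to the cutoff
    while (nb > 1 && min(dist(centers)) < 4 * a)
      centers <- matrix(runif(2 * nb, -0.8, 0.8), nb, 2)
    pos <- do.call(rbind, lapply(seq_len(nb), function(b)
      sweep(matrix(runif(2 * sample(3:8, 1), -0.1 * a, 0.1 * a), ncol = 2),
            2, centers[b, ], "+")))
    expect_equal(nClusters(clusterParticles(pos, alpha = a)),
                 bruteClusterCount(pos, a))
  }
})

test_that("cluster labels are invariant under particle order", {
  set.seed(5)
  pos <- rbind(matrix(runif(30, 0, 0.001), 15, 2),
               matrix(runif(30, 0, 0.001) + 0.5, 15, 2))
  lab1 <- clusterParticles(pos, alpha = 0.02)
  perm <- sample(30)
  lab2 <- clusterParticles(pos[perm, ], alpha = 0.02)
  back <- integer(30); back[perm] <- lab2@id
  expect_true(samePartition(lab1@id, back))
})

test_that("the multilevel mask paints cluster means at original pixels", {
  # one global cluster -> constant image at the global mean
  ens <- latticeEnsemble(3, 4, feat = 0)
  ens@features <- seq(0, 1, length.out = 12)
  ens@positions <- matrix(0.1, 12, 2)
  lab <- clusterParticles(ens)
  ml <- buildMultilevelMask(lab, ens)
  expect_equal(grayValues(ml), matrix(mean(ens@features), 3, 4))

  # two clusters with features {0,0} and {1,1} -> a two-level image
  ens2 <- makeEnsemble(rbind(c(0, 0), c(0, 0), c(0.9, 0.9), c(0.9, 0.9)),
                       c(0, 0, 1, 1), dim = c(2, 2), spacing = 0.1)
  ml2 <- buildMultilevelMask(clusterParticles(ens2, alpha = 0.1), ens2)
  expect_setequal(as.vector(grayValues(ml2)), c(0, 1))

  # a cluster {0.2, 0.4, 0.6} writes 0.4 at all three original pixels
  ens3 <- makeEnsemble(rbind(c(0, 0), c(0, 0), c(0, 0), c(0.8, 0.8)),
                       c(0.2, 0.4, 0.6, 0.9), dim = c(2, 2), spacing = 0.1)
  lab3 <- clusterParticles(ens3, alpha = 0.1)
  expect_equal(lab3@meanFeature, c(0.4, 0.9))
  expect_equal(as.vector(buildMultilevelMask(lab3, ens3)@values),
               c(0.4, 0.4, 0.4, 0.9))
})

test_that("ROI percentile threshold follows the interpolation convention", {
  img <- new("GrayImage", values = matrix(seq(0.1, 1, by = 0.1), 2, 5),
             raw = NULL)
  gtAll <- new("BinaryMask", values = matrix(1L, 2, 5))
  expect_equal(roiPercentileThreshold(img, gtAll, 10), 0.19)
  expect_equal(roiPercentileThreshold(img, gtAll, 0), 0.1)

  # constant foreground returns that constant
  flat <- new("GrayImage", values = matrix(0.4, 2, 5), raw = NULL)
  gtPart <- new("BinaryMask", values = matrix(c(1L, 1L, rep(0L, 8)), 2, 5))
  expect_equal(roiPercentileThreshold(flat, gtPart, 10), 0.4)

  empty <- new("BinaryMask", values = matrix(0L, 2, 5))
  expect_error(roiPercentileThreshold(img, empty, 10), "empty foreground")
})

test_that("binarization is closed at the threshold", {
  img <- new("GrayImage", values = matrix(c(0, 0.3, 0.5, 1), 2, 2), raw = NULL)
  expect_true(all(maskValues(binarize(img, 0)) == 1L))
  expect_true(all(maskValues(binarize(img, 1 - 1e-9))[1:3] == 0L))
  expect_equal(maskValues(binarize(img, 0.5)),
               matrix(c(0L, 0L, 1L, 1L), 2, 2))  # value == threshold -> 1
})

test_that("morphological refinement removes islands, fills holes, and is idempotent", {
  m <- matrix(0L, 12, 12)
  m[4:9, 4:9] <- 1L
  m[1, 1] <- 1L        # 1-pixel island
  m[6, 6] <- 0L        # 1-pixel hole
  out <- maskValues(morphologicalRefine(new("BinaryMask", values = m), 2, 2))
  expect_equal(out[1, 1], 0L)
  expect_equal(out[6, 6], 1L)
  expected <- matrix(0L, 12, 12); expected[4:9, 4:9] <- 1L
  expect_equal(out, expected)

  # zero minimum sizes are the identity
  expect_equal(maskValues(morphologicalRefine(new("BinaryMask", values = m),
                                              0, 0)), m)

  # idempotence on random masks
  set.seed(9)
  for (k in 1:5) {
    bm <- new("BinaryMask", values = randomMask(20, 20, 0.45))
    once <- morphologicalRefine(bm, 5, 5)
    twice <- morphologicalRefine(once, 5, 5)
    expect_identical(maskValues(twice), maskValues(once))
  }
})

test_that("component labeling matches the EBImage 4-connectivity oracle", {
  set.seed(31)
  for (k in 1:5) {
    m <- randomMask(15, 15, 0.4)
    mine <- kinseg:::labelComponents(m, 4L)
    ref <- EBImage::bwlabel(m)
    expect_true(samePartition(mine[m == 1L], as.integer(ref)[m == 1L]))
  }
  # diagonal pixels connect only under 8-connectivity
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(max(kinseg:::labelComponents(d, 4L)), 2L)
  expect_equal(max(kinseg:::labelComponents(d, 8L)), 1L)
})

test_that("a blur-free square is segmented exactly by noiseless consensus", {
  fx <- makeGeometricFixture("square", size = 48, blurScale = 0, seed = 1)
  p <- kineticParams(0.5, 0.95, 0, dt = 0.5, tMax = 20)
  res <- segment(fx$image, p, gtMask = fx$mask, seed = 7)
  expect_identical(maskValues(segmentationMask(res)), maskValues(fx$mask))
})

test_that("a single global cluster yields an all-ones mask at its own threshold", {
  fx <- makeGeometricFixture("square", size = 32, blurScale = 0, seed = 1)
  p <- kineticParams(3, 1, 0, dt = 0.5, tMax = 30)
  res <- segment(fx$image, p, gtMask = fx$mask, seed = 3)
  expect_equal(nClusters(res@labeling), 1)
  expect_true(all(maskValues(segmentationMask(res)) == 1L))
})

test_that("the pipeline is deterministic given a seed", {
  fx <- makeGeometricFixture("square", size = 32, blurScale = 0.1, seed = 6)
  p <- kineticParams(0.6, 0.2, 0.05, dt = 0.2, tMax = 10)
  a <- segment(fx$image, p, gtMask = fx$mask, seed = 5)
  b <- segment(fx$image, p, gtMask = fx$mask, seed = 5)
  expect_identical(maskValues(segmentationMask(a)),
                   maskValues(segmentationMask(b)))
  expect_identical(grayValues(multilevelMask(a)), grayValues(multilevelMask(b)))
  expect_identical(dim(maskValues(a@mask)), dim(grayValues(fx$image)))
})
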