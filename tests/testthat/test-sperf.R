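# Coordinate-network core: Huber loss, rescale trick, coordinate
# construction, training, synthesis and merging.

test_that("Huber loss matches the piecewise closed form and is monotone", {
  expect_equal(huberLoss(0), 0)
  expect_equal(huberLoss(0.5), 0.125)
  expect_equal(huberLoss(2), 1.5)
  # brute-force oracle on a dense residual grid, several deltas
  for (delta in c(0.5, 1, 2.5)) {
    a <- seq(-6, 6, by = 0.01)
    oracle <- vapply(a, function(ai)
      if (abs(ai) < delta) 0.5 * ai^2 else delta * (abs(ai) - delta / 2),
      numeric(1))
    expect_equal(huberLoss(a, delta), oracle)
    expect_true(all(diff(huberLoss(a[a >= 0], delta)) >= 0))
  }
  # continuously differentiable at |a| = delta
  eps <- 1e-7
  dLeft <- (huberLoss(1) - huberLoss(1 - eps)) / eps
  dRight <- (huberLoss(1 + eps) - huberLoss(1)) / eps
  expect_equal(dLeft, dRight, tolerance = 1e-5)
  expect_error(huberLoss(1, delta = 0), "positive")
})

test_that("rescale trick duplicates pixels up and selects top-left down", {
  expect_equal(rescaleUp(matrix(5)), matrix(5, 2, 2))
  expect_equal(rescaleDown(matrix(c(1, 3, 2, 4), 2, 2)), matrix(1))

  set.seed(8)
  x <- matrix(rpois(12 * 10, 20), 12, 10)
  up <- rescaleUp(x)
  expect_equal(dim(up), c(24, 20))
  expect_equal(sum(up), 4 * sum(x))
  for (k in 1:20) {
    i <- sample(12, 1); j <- sample(10, 1)
    expect_equal(up[2 * i - 1, 2 * j - 1], x[i, j])
  }
  expect_identical(rescaleDown(up), x)          # round trip, exact
  expect_equal(rescaleDown(matrix(7, 4, 4)), matrix(7, 2, 2))
  expect_error(rescaleDown(matrix(0, 3, 4)), "shape error")
})

test_that("coordinate batches have the right size and normalization", {
  g <- makeOrbit(6, radiusMm = 250, nU = 8, nV = 8, pixelMm = 4.8)
  co <- buildCoordinates(g, viewAngles(g)[1:4], c(8, 8))
  expect_equal(nrow(co), 8 * 8 * 4)
  expect_lt(max(abs(co[, "sin"]^2 + co[, "cos"]^2 - 1)), 1e-12)
  expect_true(all(co[, c("x", "y")] >= -1 & co[, c("x", "y")] <= 1))
  expect_true(all(co[, "r"] == 1))              # circular orbit

  ge <- makeOrbit(8, orbit = "elliptical", aMm = 300, bMm = 200,
                  nU = 4, nV = 4, pixelMm = 4.8)
  ce <- buildCoordinates(ge, viewAngles(ge), c(4, 4))
  expect_true(all(ce[, "r"] > 0 & ce[, "r"] <= 1))
  expect_equal(max(ce[, "r"]), 1)
  expect_error(buildCoordinates(g, numeric(0), c(8, 8)), "argument error")
})

test_that("training fits a constant field; synthesis is consistent at measured angles", {
  g <- makeOrbit(10, radiusMm = 200, nU = 16, nV = 16, pixelMm = 10)
  ps <- projectionSet(array(7, c(16, 16, 10)), g)
  cfg <- trainConfig(lr = 3e-3, epochs = 600, hiddenLayers = 3,
                     hiddenUnits = 32, rescale = FALSE, batchCoords = 256,
                     schedPatience = 100)
  m <- trainSperf(ps, cfg, seed = 11)
  # skipped angles: constant recovered everywhere within 1%
  syn <- synthesizeViews(m, g, viewAngles(g)[c(2, 5)])
  expect_lt(max(abs(counts(syn) - 7)) / 7, 0.01)
  expect_true(all(counts(syn) >= 0))
  # querying a measured (training) angle reproduces the constant too
  atTrain <- synthesizeViews(m, g, viewAngles(g)[1])
  expect_lt(max(abs(counts(atTrain) - 7)) / 7, 0.01)
  # empty skipped set and out-of-range angles
  expect_equal(nViews(synthesizeViews(m, g, numeric(0))), 0)
  expect_error(synthesizeViews(m, g, 7.0), "argument error")
})

test_that("training recovers a smooth separable field at held-out views", {
  full <- smoothField(60, 16)
  down <- downsampleViews(full, 2)
  cfg <- trainConfig(epochs = 50, hiddenLayers = 4, hiddenUnits = 64,
                     rescale = FALSE, batchCoords = 256)
  m <- trainSperf(down$kept, cfg, seed = 5)
  syn <- synthesizeViews(m, geometry(full), down$skippedAngles)
  ref <- counts(full)[, , down$skippedIdx]
  expect_lt(nrmsd(ref, counts(syn)), 0.10)
})

test_that("the validation split is exactly 20% and training is reproducible", {
  full <- smoothField(20, 8)
  cfg <- trainConfig(epochs = 5, hiddenLayers = 2, hiddenUnits = 16,
                     rescale = FALSE, batchCoords = 200)
  m1 <- trainSperf(full, cfg, seed = 42)
  m2 <- trainSperf(full, cfg, seed = 42)
  expect_identical(trainLog(m1)$val, trainLog(m2)$val)
  expect_identical(m1@weights, m2@weights)
  # rows: 8 * 8 * 20 = 1280; val = round(0.2 * 1280) = 256 -> train 1024;
  # visible as the per-epoch batch count in the log times batch size
  expect_equal(nrow(trainLog(m1)), 5)
  # direct check of split arithmetic on the stored normalization grid
  n <- prod(m1@normalization$gridDim) * 20
  expect_equal(round(0.2 * n), 256)

  oneView <- new("AcquisitionGeometry", angles = 0, radii = 100,
                 nU = 8L, nV = 8L, pixelMm = 10)
  expect_error(trainSperf(projectionSet(array(1, c(8, 8, 1)), oneView),
                          cfg), "insufficient data")
})

test_that("rescaled training round-trips through synthesis dimensions", {
  full <- smoothField(12, 8)
  cfg <- trainConfig(epochs = 3, hiddenLayers = 2, hiddenUnits = 8,
                     rescale = TRUE, batchCoords = 500)
  m <- trainSperf(full, cfg, seed = 1)
  expect_equal(m@normalization$gridDim, c(16L, 16L))   # doubled grid
  syn <- synthesizeViews(m, geometry(full), viewAngles(full)[2:3])
  expect_equal(dim(counts(syn)), c(8, 8, 2))           # downscaled back
  expect_true(all(counts(syn) >= 0))
})

test_that("merging measured and synthesized views preserves both", {
  g <- makeOrbit(120, radiusMm = 250, nU = 8, nV = 4, pixelMm = 4.8)
  full <- projectionSet(array(as.numeric(rpois(8 * 4 * 120, 30)),
                              c(8, 4, 120)), g)
  d <- downsampleViews(full, 4)
  fake <- projectionSet(array(1, c(8, 4, 90)),
                        geometrySubset(g, d$skippedIdx),
                        provenance = "synthesized")
  merged <- mergeViews(d$kept, fake)
  expect_equal(nViews(merged), 120)
  expect_equal(sum(provenance(merged) == "measured"), 30)
  expect_equal(sum(provenance(merged) == "synthesized"), 90)
  expect_false(is.unsorted(viewAngles(merged), strictly = TRUE))
  keptIdx <- which(provenance(merged) == "measured")
  expect_equal(counts(merged)[, , keptIdx], counts(d$kept),
               ignore_attr = FALSE, tolerance = 0)  # bit-identical values

  emptySyn <- projectionSet(array(0, c(8, 4, 0)),
                            sperf:::geometrySubset(g, integer(0)),
                            provenance = character(0))
  expect_identical(mergeViews(full, emptySyn), full)
  expect_error(mergeViews(d$kept, d$kept), "merge error")
})

test_that("photopeak and scatter models are independent objects", {
  full <- smoothField(12, 8)
  scat <- projectionSet(counts(full) * 0.3, geometry(full),
                        window = "scatter_sum")
  cfg <- trainConfig(epochs = 2, hiddenLayers = 2, hiddenUnits = 8,
                     rescale = FALSE, batchCoords = 500)
  mP <- trainSperf(full, cfg, seed = 1)
  mS <- trainSperf(scat, cfg, seed = 2)
  expect_false(identical(mP@weights, mS@weights))
  expect_equal(windowLabel(full), mP@window)
  expect_equal(mS@window, "scatter_sum")
})
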