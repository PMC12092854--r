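# Phantom voxelization, acquisition simulation (scatter windows, Poisson
# statistics) and view down-sampling.

test_that("default phantom reproduces the 6.3:1 sphere-to-background ratio", {
  ph <- makePhantom(phantomSpec(nXY = 64, nZ = 32, voxelMm = 4.8,
                                bodyAxialMm = 140))
  act <- voxelValues(ph$activity)
  body <- voxelValues(ph$mu) > 0
  ratio <- max(act[body]) / min(act[body])
  expect_equal(ratio, 0.22 / 0.035, tolerance = 1e-12)  # ~6.29
  expect_equal(round(ratio, 1), 6.3)
})

test_that("zero-concentration phantom has zero activity but nonzero mu", {
  ph <- makePhantom(phantomSpec(nXY = 32, nZ = 16, voxelMm = 9.6,
                                backgroundConc = 0, sphereConc = 0))
  expect_equal(max(voxelValues(ph$activity)), 0)
  expect_gt(max(voxelValues(ph$mu)), 0)
})

test_that("voxelized sphere volumes match their analytic volumes", {
  ph <- makePhantom(phantomSpec(nXY = 128, nZ = 48, voxelMm = 4.8))
  voxMl <- (4.8 / 10)^3
  v114 <- sum(ph$vois$sphere_114mL@mask) * voxMl
  expect_lt(abs(v114 - 114) / 114, 0.05)
  # total activity within voxelization error of the analytic spec total
  spec <- phantomSpec(nXY = 128, nZ = 48, voxelMm = 4.8)
  a <- spec$bodyAxesMm[1] / 2; b <- spec$bodyAxesMm[2] / 2
  bodyMl <- pi * a * b * spec$bodyAxialMm / 1000
  sphMl <- sum(spec$sphereVolumesMl)
  analytic <- spec$backgroundConc * (bodyMl - sphMl) +
    spec$sphereConc * sphMl
  total <- sum(voxelValues(ph$activity)) * voxMl
  expect_lt(abs(total - analytic) / analytic, 0.05)
})

test_that("background mask is inside the body and avoids dilated spheres", {
  ph <- makePhantom(phantomSpec(nXY = 64, nZ = 32, voxelMm = 4.8,
                                bodyAxialMm = 140))
  bkg <- ph$vois$BKG@mask
  expect_true(all(voxelValues(ph$mu)[bkg] > 0))
  for (nm in grep("^sphere", names(ph$vois), value = TRUE))
    expect_equal(sum(bkg & ph$vois[[nm]]@mask), 0)
  expect_error(phantomSpec(nXY = 64, nZ = 32, sphereRingMm = 200),
               "outside the body")
})

test_that("scatter-free simulation leaves scatter windows empty", {
  ph <- makePhantom(phantomSpec(nXY = 32, nZ = 8, voxelMm = 9.6,
                                bodyAxialMm = 60, sphereRingMm = 40,
                                sphereVolumesMl = c(8, 30)))
  g <- makeOrbit(8, radiusMm = 250, nU = 32, nV = 8, pixelMm = 9.6)
  sim <- simulateAcquisition(ph$activity, ph$mu, g, scatterFraction = 0,
                             seed = 4, poisson = FALSE)
  expect_equal(max(counts(sim$scatter_lower)), 0)
  expect_equal(max(counts(sim$scatter_upper)), 0)
  noiseless <- forwardProject(ph$activity, g, ph$mu)
  expect_equal(counts(sim$photopeak), counts(noiseless))
})

test_that("simulation is reproducible and Poisson-distributed", {
  ph <- makePhantom(phantomSpec(nXY = 32, nZ = 8, voxelMm = 9.6,
                                bodyAxialMm = 60, sphereRingMm = 40,
                                sphereVolumesMl = c(8, 30)))
  g <- makeOrbit(6, radiusMm = 250, nU = 32, nV = 8, pixelMm = 9.6)
  a <- simulateAcquisition(ph$activity, ph$mu, g, dwellS = 50,
                           sensitivity = 5, seed = 99)
  b <- simulateAcquisition(ph$activity, ph$mu, g, dwellS = 50,
                           sensitivity = 5, seed = 99)
  expect_identical(counts(a$photopeak), counts(b$photopeak))

  # dispersion index over seeds ~ 1 for bins with mean >= 20, and
  # doubling the dwell doubles the mean (within Monte Carlo error)
  expected <- counts(forwardProject(ph$activity, g, ph$mu,
                                    dwellS = 50, sensitivity = 5))
  sel <- which(expected >= 20)[1:25]
  draws <- sapply(1:200, function(s)
    counts(simulateAcquisition(ph$activity, ph$mu, g, dwellS = 50,
                               sensitivity = 5, scatterFraction = 0,
                               seed = s)$photopeak)[sel])
  disp <- apply(draws, 1, function(x) var(x) / mean(x))
  expect_true(all(disp > 0.75 & disp < 1.3))   # per-bin, 200 seeds
  expect_true(mean(disp) > 0.9 && mean(disp) < 1.1)
  m1 <- rowMeans(draws)
  se <- sqrt(expected[sel] / 200)
  expect_true(all(abs(m1 - expected[sel]) < 4 * se))

  draws2 <- sapply(1:200, function(s)
    counts(simulateAcquisition(ph$activity, ph$mu, g, dwellS = 100,
                               sensitivity = 5, scatterFraction = 0,
                               seed = 1000 + s)$photopeak)[sel])
  se2 <- sqrt(2 * expected[sel] / 200)
  expect_true(all(abs(rowMeans(draws2) - 2 * expected[sel]) < 3.5 * se2))
})

test_that("view down-sampling keeps every DF-th view and returns the rest", {
  g <- makeOrbit(120, radiusMm = 250, nU = 8, nV = 4, pixelMm = 4.8)
  ps <- projectionSet(array(runif(8 * 4 * 120), c(8, 4, 120)), g)

  d4 <- downsampleViews(ps, 4)
  expect_equal(nViews(d4$kept), 30)
  expect_equal(length(d4$skippedAngles), 90)
  expect_equal(sort(c(viewAngles(d4$kept), d4$skippedAngles)),
               viewAngles(g))

  d1 <- downsampleViews(ps, 1)
  expect_identical(counts(d1$kept), counts(ps))
  expect_equal(length(d1$skippedAngles), 0)

  d8 <- downsampleViews(ps, 8)
  expect_equal(nViews(d8$kept), 15)
  expect_equal(viewAngles(d8$kept), viewAngles(g)[seq(1, 120, by = 8)])

  expect_error(downsampleViews(ps, 7), "argument error")
})
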