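# TEW scatter estimation and OS-EM reconstruction, including equivalence
# with an independently coded MLEM oracle.

test_that("TEW estimate follows the window-width formula", {
  g <- smallGeom(4, 8, 4)
  mk <- function(val) projectionSet(array(val, c(8, 4, 4)), g,
                                    window = "scatter_lower")
  expect_equal(max(counts(tewScatterEstimate(mk(0), mk(0)))), 0)
  # the 20%/10% windows at 208 keV: widths 41.6 and 20.8 keV
  est <- tewScatterEstimate(mk(10), mk(10), wLowKeV = 20.8,
                            wUpKeV = 20.8, wPeakKeV = 41.6)
  expect_equal(counts(est), array(20, c(8, 4, 4)))
  # halving both scatter widths doubles the estimate
  est2 <- tewScatterEstimate(mk(10), mk(10), wLowKeV = 10.4,
                             wUpKeV = 10.4, wPeakKeV = 41.6)
  expect_equal(counts(est2), 2 * counts(est))
  expect_error(tewScatterEstimate(mk(1), mk(1), wLowKeV = 0), "parameter")
})

test_that("scalar EM update and zero-data behaviour are exact", {
  # 1-voxel/1-bin analogue on the smallest grid: a single update takes
  # x from x0 to backproj(y / fwd(x0)) / sens * x0 = y / A
  g <- new("AcquisitionGeometry", angles = c(0, pi), radii = c(100, 100),
           nU = 1L, nV = 1L, pixelMm = 10)
  ps <- projectionSet(array(8, c(1, 1, 2)), g)
  # A maps the single voxel with weight dwell*sens*volume = 2 per view
  rr <- osem(ps, NULL, g, cfg = reconConfig(1, 1, 1e-12, 1),
             dwellS = 2, sensitivity = 1, voxelNy = 1)
  expect_equal(as.numeric(voxelValues(checkpoint(rr, 1))), 8 / 2,
               tolerance = 1e-9)

  # all-zero projections collapse to zero after one iteration
  g2 <- smallGeom(6, 15, 5)
  zero <- projectionSet(array(0, c(15, 5, 6)), g2)
  rz <- osem(zero, cfg = reconConfig(2, 1, 1e-8, 1))
  expect_equal(max(voxelValues(checkpoint(rz, 1))), 0)
})

test_that("OS-EM with one subset matches an independent MLEM oracle", {
  nx <- 16; nz <- 8; nv <- 8
  g <- makeOrbit(nv, radiusMm = 150, nU = nx, nV = nz, pixelMm = 10)
  act <- circleActivity(nx, nz, seed = 33)
  mu <- voxelVolume(0.05 * (voxelValues(act) > 0.2), 10, "attenuation")
  psf <- psfModel(4, 0.02)
  y <- forwardProject(act, g, mu, psf)       # noiseless consistent data

  cfgOsem <- reconConfig(1, 16, 1e-9, 1)
  onesInit <- voxelVolume(array(1, c(nx, nx, nz)), 10, "reconstruction")
  rr <- osem(y, NULL, g, mu, psf, cfgOsem, init = onesInit)

  # independent MLEM loop coded from the update formula, using only the
  # package's projector primitives
  ones <- projectionSet(array(1, dim(counts(y))), g)
  sens <- voxelValues(backProject(ones, g, mu, psf))
  x <- array(1, c(nx, nx, nz))
  eps <- 1e-9
  loglik <- numeric(16)
  for (it in 1:16) {
    fp <- counts(forwardProject(voxelVolume(x, 10, "activity"), g, mu, psf))
    ratio <- counts(y) / (fp + eps)
    bp <- voxelValues(backProject(projectionSet(ratio, g), g, mu, psf))
    upd <- bp / pmax(sens, eps)
    upd[sens <= 0] <- 0
    x <- x * upd
    fp2 <- counts(forwardProject(voxelVolume(x, 10, "activity"), g, mu, psf))
    loglik[it] <- sum(counts(y) * log(fp2 + eps) - fp2)
    xo <- voxelValues(checkpoint(rr, it))
    expect_lt(max(abs(x - xo)) / max(x), 1e-8)
  }
  # Poisson log-likelihood nondecreasing on consistent data
  expect_true(all(diff(loglik) > -1e-6 * abs(loglik[1])))
  # all checkpoints nonnegative
  for (it in checkpointIterations(rr))
    expect_true(all(voxelValues(checkpoint(rr, it)) >= 0))
})

test_that("subset mismatch and scatter-dimension mismatch are config errors", {
  g <- smallGeom(6, 15, 5)
  ps <- projectionSet(array(1, c(15, 5, 6)), g)
  expect_error(osem(ps, cfg = reconConfig(4, 1)), "config error")
  badScat <- projectionSet(array(1, c(15, 5, 3)), smallGeom(3, 15, 5),
                           window = "scatter_sum")
  expect_error(osem(ps, badScat, cfg = reconConfig(2, 1)), "config error")
})

test_that("scatter enters the denominator additively", {
  # with a flat scatter estimate equal to half the true projections, the
  # converged activity on consistent data is halved
  g <- smallGeom(4, 15, 1)
  act <- circleActivity(15, 1, seed = 3)
  y <- forwardProject(act, g)
  sc <- projectionSet(counts(y) / 2, g, window = "scatter_sum")
  ps <- projectionSet(counts(y), g)
  rr <- osem(ps, sc, g, cfg = reconConfig(1, 40, 1e-9, 40))
  rrNo <- osem(ps, NULL, g, cfg = reconConfig(1, 40, 1e-9, 40))
  v <- voxelValues(checkpoint(rr, 40)); vN <- voxelValues(checkpoint(rrNo, 40))
  sel <- voxelValues(act) > 0.5
  expect_lt(median(abs(v[sel] / vN[sel] - 0.5)), 0.05)
})
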