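# Small in-code fixtures shared across tests.

# random activity confined to the inscribed circle (so push-rotation
# conserves mass exactly) on an nx x nx x nz grid
circleActivity <- function(nx, nz, voxelMm = 10, seed = 11) {
  set.seed(seed)
  act <- array(runif(nx * nx * nz), c(nx, nx, nz))
  xs <- seq_len(nx) - (nx + 1) / 2
  r2 <- outer(xs, xs, function(a, b) a^2 + b^2)
  for (z in seq_len(nz)) act[, , z][r2 > (nx / 2 - 2)^2] <- 0
  voxelVolume(act, voxelMm, "activity")
}

smallGeom <- function(nViews = 8, nx = 15, nz = 5, voxelMm = 10,
                      radiusMm = 200) {
  makeOrbit(nViews, radiusMm = radiusMm, nU = nx, nV = nz,
            pixelMm = voxelMm)
}

# separable smooth projection field f(x, y, theta) = A (1 + sin theta)
# g(x) g(y): an idealized noiseless sinogram used for recovery tests
smoothField <- function(nViews = 60, n = 16, amp = 50) {
  g <- makeOrbit(nViews, radiusMm = 200, nU = n, nV = n, pixelMm = 10)
  xs <- seq(-1, 1, length.out = n)
  gf <- exp(-xs^2 / 0.3)
  cts <- array(0, c(n, n, nViews))
  for (v in seq_len(nViews))
    cts[, , v] <- amp * (1 + sin(viewAngles(g)[v])) * outer(gf, gf)
  projectionSet(cts, g)
}

# dense ray-marching line-integral oracle for a single detector bin at
# view angle theta: marches from the volume border toward the detector,
# sampling activity and mu at nearest voxel centers
rayMarchOracle <- function(act, mu, voxelMm, theta, uIdx, zIdx,
                           step = 0.01) {
  nx <- dim(act)[1]; ny <- dim(act)[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # ray: all points whose rotated x equals the bin's u; sample along w
  uMm <- (uIdx - cx) * voxelMm
  ws <- seq((0.5 - cy) * voxelMm, (ny + 0.5 - cy) * voxelMm,
            by = step * voxelMm)
  total <- 0
  for (wMm in ws) {
    x <- uMm * cos(theta) + wMm * sin(theta)
    y <- -uMm * sin(theta) + wMm * cos(theta)
    i <- round(x / voxelMm + cx); j <- round(y / voxelMm + cy)
    if (i < 1 || i > nx || j < 1 || j > ny) next
    a <- act[i, j, zIdx]
    if (a == 0) next
    # attenuation integral from this point to the detector (w' > w)
    wAtt <- seq(wMm, (ny + 0.5 - cy) * voxelMm, by = step * voxelMm)
    muInt <- 0
    for (w2 in wAtt[-1]) {
      x2 <- uMm * cos(theta) + w2 * sin(theta)
      y2 <- -uMm * sin(theta) + w2 * cos(theta)
      i2 <- round(x2 / voxelMm + cx); j2 <- round(y2 / voxelMm + cy)
      if (i2 >= 1 && i2 <= nx && j2 >= 1 && j2 <= ny)
        muInt <- muInt + mu[i2, j2, zIdx] * step * voxelMm / 10
    }
    total <- total + a * exp(-muInt) * step
  }
  total  # in units of (activity sum along ray) with voxel-length steps
}
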