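## Digital hot-sphere phantom and acquisition simulator: the synthetic
## stand-in for a Lu-177 phantom acquisition with photopeak and adjacent
## scatter windows, Poisson counting noise, attenuation and depth-dependent
## collimator blur.

#' Describe a hot-sphere phantom
#'
#' An elliptical-cylinder "body" of warm background activity containing hot
#' sphere inserts, with uniform attenuation inside the body. Sphere radii
#' derive from their fill volumes, \code{r = (3V / 4 pi)^(1/3)}.
#'
#' The defaults emulate a Lu-177 quantification phantom: six hot spheres of
#' 2, 4, 8, 16, 30 and 114 mL at 0.22 MBq/mL in a 0.035 MBq/mL background
#' (sphere-to-background ratio 6.3:1), uniform water-like attenuation of
#' 0.135 1/cm at 208 keV, a 300 x 220 mm elliptical body cross-section, and
#' a 128 x 128 matrix with 4.8 mm voxels. Spheres are placed on a
#' transaxial ring at the phantom mid-plane.
#'
#' @param nXY transaxial matrix size (square).
#' @param nZ number of axial slices.
#' @param voxelMm isotropic voxel size (mm).
#' @param bodyAxesMm full transaxial axes of the body ellipse (mm).
#' @param bodyAxialMm axial extent of the body (mm).
#' @param backgroundConc warm background concentration (MBq/mL).
#' @param sphereVolumesMl hot-sphere fill volumes (mL).
#' @param sphereConc hot-sphere concentration (MBq/mL).
#' @param sphereRingMm radius of the transaxial ring the sphere centers sit
#'   on (mm).
#' @param muBody uniform attenuation inside the body (1/cm).
#' @param bkgErodeVox,sphereDilateVox background-mask margins in voxels:
#'   the background region is the body eroded by \code{bkgErodeVox} minus
#'   all spheres dilated by \code{sphereDilateVox}, so it never overlaps
#'   the hot-sphere VOIs.
#' @return a \code{PhantomSpec} (validated list).
#' @examples
#' spec <- phantomSpec(nXY = 64, nZ = 32)
#' @export
phantomSpec <- function(nXY = 128L, nZ = 48L, voxelMm = 4.8,
                        bodyAxesMm = c(300, 220), bodyAxialMm = 200,
                        backgroundConc = 0.035,
                        sphereVolumesMl = c(2, 4, 8, 16, 30, 114),
                        sphereConc = 0.22,
                        sphereRingMm = 65,
                        muBody = 0.135,
                        bkgErodeVox = 2L, sphereDilateVox = 1L) {
  spec <- list(nXY = as.integer(nXY), nZ = as.integer(nZ),
               voxelMm = voxelMm, bodyAxesMm = bodyAxesMm,
               bodyAxialMm = bodyAxialMm, backgroundConc = backgroundConc,
               sphereVolumesMl = sphereVolumesMl, sphereConc = sphereConc,
               sphereRingMm = sphereRingMm, muBody = muBody,
               bkgErodeVox = as.integer(bkgErodeVox),
               sphereDilateVox = as.integer(sphereDilateVox))
  if (any(c(backgroundConc, sphereConc) < 0))
    stop("spec error: concentrations must be nonnegative")
  if (any(sphereVolumesMl <= 0)) stop("spec error: sphere volumes positive")
  if (muBody < 0) stop("spec error: muBody must be nonnegative")
  ## sphere centers: evenly spread on the ring at the axial mid-plane
  ns <- length(sphereVolumesMl)
  ang <- 2 * pi * (seq_len(ns) - 1) / max(ns, 1)
  spec$sphereCentersMm <- cbind(x = sphereRingMm * cos(ang),
                                y = sphereRingMm * sin(ang), z = 0)
  spec$sphereRadiiMm <- (3 * sphereVolumesMl * 1000 / (4 * pi))^(1 / 3)
  a <- bodyAxesMm[1] / 2; b <- bodyAxesMm[2] / 2
  for (s in seq_len(ns)) {
    cx <- spec$sphereCentersMm[s, "x"]; cyy <- spec$sphereCentersMm[s, "y"]
    r <- spec$sphereRadiiMm[s]
    ## conservative containment: grown ellipse test on the sphere surface
    if ((cx / (a - r))^2 + (cyy / (b - r))^2 > 1 ||
        abs(spec$sphereCentersMm[s, "z"]) + r > bodyAxialMm / 2)
      stop("spec error: sphere ", s, " extends outside the body")
  }
  class(spec) <- "PhantomSpec"
  spec
}

## 6-neighbour binary erosion/dilation, k passes
binErode <- function(m, k) {
  for (p in seq_len(k)) {
    d <- dim(m); nx <- d[1]; ny <- d[2]; nz <- d[3]
    out <- m
    out[-1, , ] <- out[-1, , ] & m[-nx, , ]
    out[-nx, , ] <- out[-nx, , ] & m[-1, , ]
    out[, -1, ] <- out[, -1, ] & m[, -ny, ]
    out[, -ny, ] <- out[, -ny, ] & m[, -1, ]
    out[, , -1] <- out[, , -1] & m[, , -nz]
    out[, , -nz] <- out[, , -nz] & m[, , -1]
    out[1, , ] <- FALSE; out[nx, , ] <- FALSE
    out[, 1, ] <- FALSE; out[, ny, ] <- FALSE
    out[, , 1] <- FALSE; out[, , nz] <- FALSE
    m <- out
  }
  m
}

binDilate <- function(m, k) {
  for (p in seq_len(k)) {
    d <- dim(m); nx <- d[1]; ny <- d[2]; nz <- d[3]
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-nx, , ]
    out[-nx, , ] <- out[-nx, , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -ny, ]
    out[, -ny, ] <- out[, -ny, ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -nz]
    out[, , -nz] <- out[, , -nz] | m[, , -1]
    m <- out
  }
  m
}

#' Voxelize a hot-sphere phantom
#'
#' Rasterizes the phantom: background concentration inside the body
#' ellipse, sphere concentrations overriding the background inside each
#' sphere radius, uniform attenuation inside the body and zero outside.
#' Also returns one VOI mask per sphere (voxels whose centers fall inside
#' the analytic sphere) plus a \code{"BKG"} mask - the body eroded by the
#' configured margin minus all dilated sphere masks.
#'
#' @param spec a \code{PhantomSpec}.
#' @return list with elements \code{activity} (VoxelVolume, MBq/mL),
#'   \code{mu} (VoxelVolume, 1/cm), and \code{vois} (list of VOIMask: one
#'   \code{sphere_<V>mL} per sphere, then \code{BKG}).
#' @examples
#' ph <- makePhantom(phantomSpec(nXY = 32, nZ = 16, voxelMm = 9.6))
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nx <- spec$nXY; ny <- spec$nXY; nz <- spec$nZ; vox <- spec$voxelMm
  ## voxel-center coordinates in mm, origin at the grid center
  xs <- (seq_len(nx) - (nx + 1) / 2) * vox
  ys <- (seq_len(ny) - (ny + 1) / 2) * vox
  zs <- (seq_len(nz) - (nz + 1) / 2) * vox
  a <- spec$bodyAxesMm[1] / 2; b <- spec$bodyAxesMm[2] / 2
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  body <- (X / a)^2 + (Y / b)^2 <= 1 & abs(Z) <= spec$bodyAxialMm / 2
  act <- array(0, c(nx, ny, nz))
  act[body] <- spec$backgroundConc
  mu <- array(0, c(nx, ny, nz))
  mu[body] <- spec$muBody
  vois <- list()
  ns <- length(spec$sphereVolumesMl)
  for (s in seq_len(ns)) {
    ctr <- spec$sphereCentersMm[s, ]
    r <- spec$sphereRadiiMm[s]
    sm <- (X - ctr["x"])^2 + (Y - ctr["y"])^2 + (Z - ctr["z"])^2 <= r^2
    act[sm] <- spec$sphereConc
    vois[[s]] <- voiMask(sm, sprintf("sphere_%gmL", spec$sphereVolumesMl[s]))
  }
  bkg <- binErode(body, spec$bkgErodeVox)
  for (s in seq_len(ns))
    bkg <- bkg & !binDilate(vois[[s]]@mask, spec$sphereDilateVox)
  vois[[ns + 1]] <- voiMask(bkg, "BKG")
  names(vois) <- vapply(vois, function(v) v@label, character(1))
  list(activity = voxelVolume(act, vox, "activity"),
       mu = voxelVolume(mu, vox, "attenuation"),
       vois = vois)
}

## Per-view 2D Gaussian blur used for the broad scatter kernel (not part
## of the system model; symmetric, normalized, zero-padded).
blurViews <- function(arr, sigmaVox) {
  bu <- blurMatrix1D(dim(arr)[1], sigmaVox)
  bz <- blurMatrix1D(dim(arr)[2], sigmaVox)
  if (is.null(bu)) return(arr)
  out <- arr
  for (v in seq_len(dim(arr)[3]))
    out[, , v] <- as.matrix(bu %*% arr[, , v] %*% bz)
  out
}

#' Simulate a multi-window SPECT acquisition
#'
#' Computes noiseless expected photopeak counts with [forwardProject()],
#' adds a scatter component (the primary convolved per view with a broad
#' Gaussian and scaled by \code{scatterFraction}), splits that component
#' equally between the two adjacent scatter windows, and draws independent
#' Poisson counts per bin and window.
#'
#' @inheritParams forwardProject
#' @param activity activity \code{VoxelVolume}.
#' @param scatterFraction scatter-to-primary ratio in the photopeak window,
#'   in \code{[0, 1)}.
#' @param scatterSigmaMm width of the broad scatter kernel (mm).
#' @param seed integer seed; the simulation is bit-reproducible for a
#'   fixed seed.
#' @param poisson set FALSE to return noiseless expected counts.
#' @return named list of \code{ProjectionSet}: \code{photopeak},
#'   \code{scatter_lower}, \code{scatter_upper}.
#' @export
simulateAcquisition <- function(activity, mu, geom, psf = NULL,
                                dwellS = 1, sensitivity = 1,
                                scatterFraction = 0.3,
                                scatterSigmaMm = 30,
                                seed = 1L, poisson = TRUE) {
  if (dwellS <= 0 || sensitivity <= 0)
    stop("parameter error: dwellS and sensitivity must be positive")
  if (scatterFraction < 0 || scatterFraction >= 1)
    stop("parameter error: scatterFraction must be in [0, 1)")
  primary <- forwardProject(activity, geom, mu = mu, psf = psf,
                            dwellS = dwellS, sensitivity = sensitivity)
  prim <- counts(primary)
  scat <- if (scatterFraction > 0) {
    blurViews(prim, scatterSigmaMm / geom@pixelMm) * scatterFraction
  } else {
    array(0, dim(prim))
  }
  expected <- list(photopeak = prim + scat,
                   scatter_lower = scat / 2,
                   scatter_upper = scat / 2)
  withLocalSeed(seed, {
    lapply(setNames(names(expected), names(expected)), function(w) {
      e <- expected[[w]]
      cts <- if (poisson) array(rpois(length(e), e), dim(e)) else e
      projectionSet(cts, geom, window = w, provenance = "measured",
                    dwellS = dwellS)
    })
  })
}

#' Sum the two scatter windows
#'
#' The training target of the scatter-window coordinate model and the
#' input to TEW correction at synthesized angles is the sum of the lower
#' and upper scatter windows.
#'
#' @param lower,upper scatter-window \code{ProjectionSet}s on the same
#'   geometry.
#' @return a \code{ProjectionSet} with window \code{"scatter_sum"}.
#' @export
scatterSum <- function(lower, upper) {
  stopifnot(identical(dim(lower@counts), dim(upper@counts)))
  projectionSet(lower@counts + upper@counts, lower@geom,
                window = "scatter_sum", provenance = lower@provenance,
                dwellS = lower@dwellS)
}

#' Down-sample an acquisition by skipping views
#'
#' Keeps every DF-th view starting at the first (indices 0, DF, 2 DF, ...),
#' emulating an acquisition in which only 1/DF of the gantry stops are
#' measured; e.g. DF = 4 on a 120-view scan keeps 30 measured views and
#' skips 90, a 75 percent reduction in scan time.
#'
#' @param proj a \code{ProjectionSet}.
#' @param DF integer down-sampling factor dividing the number of views.
#' @return list with \code{kept} (ProjectionSet of measured views) and
#'   \code{skippedAngles} (ordered radians) plus \code{skippedIdx}.
#' @export
downsampleViews <- function(proj, DF) {
  nv <- nViews(proj)
  DF <- as.integer(DF)
  if (DF < 1 || nv %% DF != 0)
    stop("argument error: DF must divide the number of views (",
         nv, " %% ", DF, " != 0)")
  keep <- seq(1L, nv, by = DF)
  skip <- setdiff(seq_len(nv), keep)
  kept <- projectionSet(proj@counts[, , keep, drop = FALSE],
                        geometrySubset(proj@geom, keep),
                        window = proj@window,
                        provenance = proj@provenance[keep],
                        dwellS = proj@dwellS)
  list(kept = kept,
       skippedAngles = proj@geom@angles[skip],
       skippedIdx = skip)
}
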