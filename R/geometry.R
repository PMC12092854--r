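## Acquisition geometry: orbits and the collimator-detector response model.

#' Construct an acquisition orbit
#'
#' Builds an \code{AcquisitionGeometry} with evenly spaced view angles over
#' \code{[0, 2*pi)}. A circular orbit keeps the detector at a constant
#' radius; an elliptical orbit follows the radius of an ellipse with the
#' given semi-axes, \code{r(theta) = a*b / sqrt((b*cos(theta))^2 +
#' (a*sin(theta))^2)}, emulating a body-contour (noncircular) orbit.
#'
#' Angle convention: theta = 0 places the detector along the +y axis of the
#' volume, with counter-clockwise positive rotation; the detector u-axis is
#' aligned with the rotated x-axis.
#'
#' @param nViews integer >= 2, number of views.
#' @param orbit \code{"circular"} or \code{"elliptical"}.
#' @param radiusMm constant radius in mm (circular orbit).
#' @param aMm,bMm ellipse semi-axes in mm at theta = 0 and theta = pi/2
#'   (elliptical orbit).
#' @param nU,nV detector matrix dimensions.
#' @param pixelMm detector pixel pitch in mm.
#' @return an \code{AcquisitionGeometry}.
#' @examples
#' makeOrbit(120, radiusMm = 250)
#' makeOrbit(8, orbit = "elliptical", aMm = 300, bMm = 200)
#' @export
makeOrbit <- function(nViews, orbit = c("circular", "elliptical"),
                      radiusMm = 250, aMm = 300, bMm = 200,
                      nU = 128L, nV = 128L, pixelMm = 4.8) {
  orbit <- match.arg(orbit)
  if (nViews < 2) stop("nViews must be >= 2")
  angles <- 2 * pi * (seq_len(nViews) - 1L) / nViews
  radii <- switch(orbit,
    circular = {
      if (radiusMm <= 0) stop("invalid geometry: radiusMm must be positive")
      rep(radiusMm, nViews)
    },
    elliptical = {
      if (aMm <= 0 || bMm <= 0)
        stop("invalid geometry: ellipse semi-axes must be positive")
      aMm * bMm / sqrt((bMm * cos(angles))^2 + (aMm * sin(angles))^2)
    }
  )
  new("AcquisitionGeometry", angles = angles, radii = radii,
      nU = as.integer(nU), nV = as.integer(nV), pixelMm = pixelMm)
}

## Geometry restricted to a subset of view indices. Angles keep their
## original values, so the subset remains strictly increasing.
geometrySubset <- function(geom, idx) {
  new("AcquisitionGeometry", angles = geom@angles[idx],
      radii = geom@radii[idx], nU = geom@nU, nV = geom@nV,
      pixelMm = geom@pixelMm)
}

#' Depth-dependent Gaussian collimator-detector response
#'
#' The collimator blur is modelled as a Gaussian whose standard deviation
#' grows linearly with the source-to-collimator distance:
#' \code{sigma(d) = sigma0Mm + slopeMmPerMm * d}. This is the usual
#' parametric stand-in for a measured point-source response fitted with
#' Gaussian curves.
#'
#' @param sigma0Mm intrinsic sigma (mm) at zero distance.
#' @param slopeMmPerMm sigma growth per mm of distance.
#' @return a \code{PSFModel}.
#' @examples
#' psf <- psfModel(2, 0.02)
#' psfSigma(psf, 100)  # 4 mm
#' @export
psfModel <- function(sigma0Mm = 2, slopeMmPerMm = 0.02) {
  new("PSFModel", sigma0Mm = sigma0Mm, slopeMmPerMm = slopeMmPerMm)
}

#' @rdname psfModel
#' @param psf a \code{PSFModel}.
#' @param dMm nonnegative source-to-collimator distance(s) in mm.
#' @export
psfSigma <- function(psf, dMm) {
  stopifnot(is(psf, "PSFModel"))
  if (any(dMm < 0)) stop("distance must be nonnegative")
  psf@sigma0Mm + psf@slopeMmPerMm * dMm
}

#' Construct a VoxelVolume
#'
#' @param values 3D nonnegative array.
#' @param voxelMm isotropic voxel size in mm.
#' @param role \code{"activity"} (MBq/mL), \code{"attenuation"} (1/cm) or
#'   \code{"reconstruction"}.
#' @return a \code{VoxelVolume}.
#' @export
voxelVolume <- function(values, voxelMm,
                        role = c("activity", "attenuation",
                                 "reconstruction")) {
  role <- match.arg(role)
  new("VoxelVolume", values = values, voxelMm = voxelMm, role = role)
}

#' Construct a ProjectionSet
#'
#' @param counts 3D array (nU, nV, nViews).
#' @param geom matching \code{AcquisitionGeometry}.
#' @param window energy-window label.
#' @param provenance per-view flag, recycled if length 1.
#' @param dwellS seconds per view.
#' @return a \code{ProjectionSet}.
#' @export
projectionSet <- function(counts, geom, window = "photopeak",
                          provenance = "measured", dwellS = 1) {
  nv <- dim(counts)[3]
  if (length(provenance) == 1L) provenance <- rep(provenance, nv)
  new("ProjectionSet", counts = counts, geom = geom, window = window,
      provenance = provenance, dwellS = dwellS)
}

#' Construct a VOIMask
#'
#' @param mask logical 3D array.
#' @param label text label.
#' @return a \code{VOIMask}.
#' @export
voiMask <- function(mask, label) new("VOIMask", mask = mask, label = label)

## Run expr with a local, seeded RNG stream; the caller's RNG state is
## untouched. All stochastic package operations funnel through this.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Deterministic sub-seed derivation so every random consumer draws from a
## named stream of one master seed.
deriveSeed <- function(master, salt) {
  salts <- c(simulate = 101L, split = 211L, train = 307L, thin = 401L,
             init = 503L, shuffle = 601L)
  s <- if (is.character(salt)) salts[[salt]] else as.integer(salt)
  as.integer((as.numeric(master) %% 50000) * 40009 + s * 97 + 13) %% 2147483647L
}
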