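## Core S4 containers shared by the simulator, the view-synthesis model and
## the reconstructor.

#' AcquisitionGeometry: gantry orbit and detector description
#'
#' Holds the per-view gantry angles and radial positions together with the
#' detector matrix description. Angles are stored in radians over
#' \code{[0, 2*pi)}; radii are detector-to-rotation-axis distances in mm, one
#' per view, so noncircular (e.g. elliptical body-contour) orbits are
#' represented naturally.
#'
#' @slot angles numeric, strictly increasing view angles in radians, all in
#'   \code{[0, 2*pi)}.
#' @slot radii numeric, positive radial position (mm) of the detector for
#'   each view.
#' @slot nU,nV integer, detector matrix dimensions (transaxial bins nU,
#'   axial bins nV).
#' @slot pixelMm numeric, detector pixel pitch in mm.
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
  representation(
    angles  = "numeric",
    radii   = "numeric",
    nU      = "integer",
    nV      = "integer",
    pixelMm = "numeric"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  n <- length(object@angles)  # zero views allowed (empty synthesis sets)
  if (length(object@radii) != n)
    msg <- c(msg, "angles and radii must have equal length")
  if (n > 0 && (any(object@angles < 0) || any(object@angles >= 2 * pi)))
    msg <- c(msg, "angles must lie in [0, 2*pi)")
  if (n > 1 && any(diff(object@angles) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (length(object@radii) && any(object@radii <= 0))
    msg <- c(msg, "all radii must be positive")
  if (object@nU < 1L || object@nV < 1L)
    msg <- c(msg, "detector matrix dimensions must be positive")
  if (object@pixelMm <= 0)
    msg <- c(msg, "pixelMm must be positive")
  if (length(msg)) msg else TRUE
})

#' PSFModel: depth-dependent collimator-detector response
#'
#' Parametric Gaussian collimator-detector response: the blur standard
#' deviation grows linearly with the source-to-collimator distance d,
#' \code{sigma(d) = sigma0Mm + slopeMmPerMm * d}.
#'
#' @slot sigma0Mm numeric, intrinsic blur sigma (mm) at zero distance.
#' @slot slopeMmPerMm numeric, growth of sigma per mm of distance.
#' @exportClass PSFModel
setClass("PSFModel",
  representation(sigma0Mm = "numeric", slopeMmPerMm = "numeric")
)

setValidity("PSFModel", function(object) {
  if (object@sigma0Mm < 0) return("sigma0Mm must be >= 0")
  if (object@slopeMmPerMm < 0) return("slopeMmPerMm must be >= 0")
  TRUE
})

#' VoxelVolume: 3D scalar grid with physical voxel size
#'
#' A 3D grid of nonnegative values on isotropic voxels. The \code{role}
#' label distinguishes activity maps (MBq/mL), attenuation maps (1/cm) and
#' reconstructed volumes.
#'
#' @slot values 3D numeric array, all values >= 0.
#' @slot voxelMm numeric, isotropic voxel size in mm.
#' @slot role character, one of \code{"activity"}, \code{"attenuation"},
#'   \code{"reconstruction"}.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(values = "array", voxelMm = "numeric", role = "character")
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "values must be nonnegative")
  if (object@voxelMm <= 0) msg <- c(msg, "voxelMm must be positive")
  if (!object@role %in% c("activity", "attenuation", "reconstruction"))
    msg <- c(msg, "role must be activity, attenuation or reconstruction")
  if (length(msg)) msg else TRUE
})

#' ProjectionSet: a stack of projection views with provenance
#'
#' Counts on an (nU, nV, nViews) grid, tagged with the energy-window role
#' and a per-view provenance flag recording whether each view was measured,
#' synthesized by the coordinate model, or linearly interpolated.
#'
#' @slot counts 3D numeric array (nU, nV, nViews) of nonnegative counts.
#' @slot geom an \code{AcquisitionGeometry} whose views match dim 3.
#' @slot window character; one of \code{"photopeak"}, \code{"scatter_lower"},
#'   \code{"scatter_upper"}, \code{"scatter_sum"}.
#' @slot provenance character vector, one of \code{"measured"},
#'   \code{"synthesized"}, \code{"interpolated"} per view.
#' @slot dwellS numeric, acquisition time per view in seconds.
#' @exportClass ProjectionSet
setClass("ProjectionSet",
  representation(
    counts     = "array",
    geom       = "AcquisitionGeometry",
    window     = "character",
    provenance = "character",
    dwellS     = "numeric"
  )
)

setValidity("ProjectionSet", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) {
    msg <- c(msg, "counts must be a 3D array (nU, nV, nViews)")
  } else {
    if (d[3] != length(object@geom@angles))
      msg <- c(msg, "third dim of counts must equal the number of views")
    if (d[1] != object@geom@nU || d[2] != object@geom@nV)
      msg <- c(msg, "counts dims 1:2 must match the detector matrix")
    if (length(object@provenance) != d[3])
      msg <- c(msg, "provenance must have one flag per view")
  }
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be nonnegative")
  if (!object@window %in%
      c("photopeak", "scatter_lower", "scatter_upper", "scatter_sum"))
    msg <- c(msg, "unknown window label")
  if (!all(object@provenance %in%
           c("measured", "synthesized", "interpolated")))
    msg <- c(msg, "unknown provenance flag")
  if (object@dwellS <= 0) msg <- c(msg, "dwellS must be positive")
  if (length(msg)) msg else TRUE
})

#' VOIMask: a labelled volume-of-interest
#'
#' Boolean 3D mask aligned to a \code{VoxelVolume}, with a free-text label
#' (e.g. \code{"sphere_114mL"} or \code{"BKG"}).
#'
#' @slot mask logical 3D array.
#' @slot label character label.
#' @exportClass VOIMask
setClass("VOIMask", representation(mask = "array", label = "character"))

setValidity("VOIMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be 3D")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "mask must be nonempty")
  if (length(msg)) msg else TRUE
})

#' SperfModel: a trained per-scan coordinate network
#'
#' Fully connected multilayer perceptron mapping the 5D projection-pixel
#' coordinate (x, y, sin theta, cos theta, r) to a nonnegative count,
#' together with the normalization constants needed to reproduce the
#' mapping at inference (coordinate scaling, target count scale, the grid
#' the model was trained on, and whether the rescale trick was applied).
#'
#' @slot weights list of weight matrices, one per layer.
#' @slot biases list of bias vectors, one per layer.
#' @slot normalization list with elements \code{rMax}, \code{targetScale},
#'   \code{gridDim} (trained view dimensions), \code{rescale}.
#' @slot window character, the energy window the model was trained on.
#' @slot trainLog data.frame with per-epoch train/validation loss.
#' @exportClass SperfModel
setClass("SperfModel",
  representation(
    weights       = "list",
    biases        = "list",
    normalization = "list",
    window        = "character",
    trainLog      = "data.frame"
  )
)

setValidity("SperfModel", function(object) {
  msg <- character()
  if (length(object@weights) < 2L)
    msg <- c(msg, "model must have at least one hidden layer")
  if (length(object@weights) != length(object@biases))
    msg <- c(msg, "weights and biases must pair up")
  if (length(object@weights)) {
    if (nrow(object@weights[[1L]]) != 5L)
      msg <- c(msg, "input width must be 5")
    if (ncol(object@weights[[length(object@weights)]]) != 1L)
      msg <- c(msg, "output width must be 1")
  }
  need <- c("rMax", "targetScale", "gridDim", "rescale")
  if (!all(need %in% names(object@normalization)))
    msg <- c(msg, paste("normalization must contain",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ReconResult: OS-EM reconstruction checkpoints
#'
#' A map from iteration number to reconstructed \code{VoxelVolume}, plus
#' the configuration and the provenance summary of the projections that
#' were reconstructed.
#'
#' @slot volumes named list of \code{VoxelVolume}, names are iteration
#'   numbers as characters.
#' @slot config list, the \code{reconConfig()} used.
#' @slot provenance character, provenance flags of the input views.
#' @exportClass ReconResult
setClass("ReconResult",
  representation(volumes = "list", config = "list", provenance = "character")
)

setValidity("ReconResult", function(object) {
  if (!length(object@volumes)) return("no checkpoints stored")
  ok <- vapply(object@volumes, function(v) is(v, "VoxelVolume"), logical(1))
  if (!all(ok)) return("volumes must all be VoxelVolume")
  TRUE
})
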