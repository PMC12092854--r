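## File interfaces: NIfTI volumes, geometry configs (degrees externally,
## radians internally), model checkpoints and metrics tables.

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as .nii/.nii.gz with the voxel size in the header.
#'
#' @param vol a \code{VoxelVolume}.
#' @param path file path (.nii or .nii.gz).
#' @param role role to assign on read.
#' @return \code{readVolume}: a \code{VoxelVolume}.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- rep(vol@voxelMm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, role = "activity") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  voxelVolume(array(as.numeric(img), dim(img)), vox, role)
}

#' Serialize acquisition geometry to a plain config mapping
#'
#' Angles are written in degrees (the external convention) and converted
#' back to radians on read.
#'
#' @param geom an \code{AcquisitionGeometry}.
#' @param path YAML file path.
#' @return \code{readGeometry}: an \code{AcquisitionGeometry}.
#' @export
writeGeometry <- function(geom, path) {
  yaml::write_yaml(list(
    angles_deg = geom@angles * 180 / pi,
    radii_mm = geom@radii,
    n_u = geom@nU, n_v = geom@nV, pixel_mm = geom@pixelMm), path)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  g <- yaml::read_yaml(path)
  new("AcquisitionGeometry",
      angles = as.numeric(g$angles_deg) * pi / 180,
      radii = as.numeric(g$radii_mm),
      nU = as.integer(g$n_u), nV = as.integer(g$n_v),
      pixelMm = as.numeric(g$pixel_mm))
}

#' Save and load a trained coordinate model
#'
#' Checkpoints carry the weights, the normalization constants and the
#' training log in a portable serialized container.
#'
#' @param model a \code{SperfModel}.
#' @param path file path (.rds).
#' @return \code{loadSperfModel}: a \code{SperfModel}.
#' @export
saveSperfModel <- function(model, path) {
  saveRDS(list(weights = model@weights, biases = model@biases,
               normalization = model@normalization,
               window = model@window, trainLog = model@trainLog),
          path)
  invisible(path)
}

#' @rdname saveSperfModel
#' @export
loadSperfModel <- function(path) {
  m <- readRDS(path)
  new("SperfModel", weights = m$weights, biases = m$biases,
      normalization = m$normalization, window = m$window,
      trainLog = m$trainLog)
}
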