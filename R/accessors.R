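## Accessors and show() methods.

#' @rdname AcquisitionGeometry-class
#' @aliases nViews,AcquisitionGeometry-method
#' @export
setMethod("nViews", "AcquisitionGeometry", function(x) length(x@angles))

#' @rdname AcquisitionGeometry-class
#' @export
setMethod("viewAngles", "AcquisitionGeometry", function(x) x@angles)

#' @rdname AcquisitionGeometry-class
#' @export
setMethod("viewRadii", "AcquisitionGeometry", function(x) x@radii)

#' @rdname ProjectionSet-class
#' @export
setMethod("nViews", "ProjectionSet", function(x) length(x@geom@angles))

#' @rdname ProjectionSet-class
#' @export
setMethod("viewAngles", "ProjectionSet", function(x) x@geom@angles)

#' @rdname ProjectionSet-class
#' @export
setMethod("counts", "ProjectionSet", function(x) x@counts)

#' @rdname ProjectionSet-class
#' @export
setMethod("geometry", "ProjectionSet", function(x) x@geom)

#' @rdname ProjectionSet-class
#' @export
setMethod("provenance", "ProjectionSet", function(x) x@provenance)

#' @rdname ProjectionSet-class
#' @export
setMethod("windowLabel", "ProjectionSet", function(x) x@window)

#' @rdname VoxelVolume-class
#' @export
setMethod("voxelValues", "VoxelVolume", function(x) x@values)

#' @rdname VoxelVolume-class
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelMm)

#' @rdname VoxelVolume-class
#' @export
setMethod("volumeRole", "VoxelVolume", function(x) x@role)

#' @rdname ReconResult-class
#' @param iteration integer iteration number of a stored checkpoint.
#' @export
setMethod("checkpoint", "ReconResult", function(x, iteration) {
  key <- as.character(iteration)
  if (!key %in% names(x@volumes))
    stop("no checkpoint stored at iteration ", iteration,
         "; available: ", paste(names(x@volumes), collapse = ", "))
  x@volumes[[key]]
})

#' @rdname ReconResult-class
#' @export
setMethod("checkpointIterations", "ReconResult",
          function(x) as.integer(names(x@volumes)))

#' @rdname SperfModel-class
#' @export
setMethod("trainLog", "SperfModel", function(x) x@trainLog)

setMethod("show", "AcquisitionGeometry", function(object) {
  r <- range(object@radii)
  cat("AcquisitionGeometry with", length(object@angles), "views\n")
  cat("  detector:", object@nU, "x", object@nV, "bins,",
      object@pixelMm, "mm pixels\n")
  cat(sprintf("  radii: %.1f..%.1f mm (%s orbit)\n", r[1], r[2],
              if (diff(r) < 1e-9) "circular" else "noncircular"))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelVolume [%s] %dx%dx%d @ %.2f mm; range [%.4g, %.4g]\n",
              object@role, d[1], d[2], d[3], object@voxelMm,
              min(object@values), max(object@values)))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@counts)
  tab <- table(object@provenance)
  cat(sprintf("ProjectionSet [%s] %dx%d pixels, %d views (%s)\n",
              object@window, d[1], d[2], d[3],
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  cat(sprintf("  total counts %.4g; dwell %.1f s/view\n",
              sum(object@counts), object@dwellS))
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf("VOIMask '%s': %d voxels\n", object@label, sum(object@mask)))
})

setMethod("show", "SperfModel", function(object) {
  widths <- vapply(object@weights, ncol, integer(1))
  cat("SperfModel (coordinate MLP), window:", object@window, "\n")
  cat("  layers: 5 ->", paste(widths, collapse = " -> "), "\n")
  if (nrow(object@trainLog))
    cat(sprintf("  best validation loss %.5g at epoch %d of %d\n",
                min(object@trainLog$val),
                which.min(object@trainLog$val), nrow(object@trainLog)))
})

setMethod("show", "ReconResult", function(object) {
  its <- names(object@volumes)
  cat("ReconResult with", length(its), "checkpoint(s) at iterations",
      paste(its, collapse = ", "), "\n")
  cat("  input views:", paste(names(table(object@provenance)),
                              table(object@provenance),
                              sep = ":", collapse = ", "), "\n")
})
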