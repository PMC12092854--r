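#' @rdname AcquisitionGeometry-class
#' @param object,x an object.
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname AcquisitionGeometry-class
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname AcquisitionGeometry-class
#' @export
setGeneric("viewRadii", function(x) standardGeneric("viewRadii"))

#' @rdname ProjectionSet-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname ProjectionSet-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname ProjectionSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ProjectionSet-class
#' @export
setGeneric("windowLabel", function(x) standardGeneric("windowLabel"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("volumeRole", function(x) standardGeneric("volumeRole"))

#' @rdname ReconResult-class
#' @export
setGeneric("checkpoint", function(x, iteration) standardGeneric("checkpoint"))

#' @rdname ReconResult-class
#' @export
setGeneric("checkpointIterations",
           function(x) standardGeneric("checkpointIterations"))

#' @rdname SperfModel-class
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))
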