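## Image-quality metrics: NRMSD, activity recovery, background noise,
## CNR and the relative measures (RCR, RCNR) against a full-view
## reconstruction.

maskValues <- function(x, mask = NULL) {
  v <- if (is(x, "VoxelVolume")) x@values
       else if (is(x, "ProjectionSet")) x@counts
       else x
  if (is.null(mask)) return(as.numeric(v))
  m <- if (is(mask, "VOIMask")) mask@mask else mask
  as.numeric(v[m])
}

#' Normalized root-mean-square difference
#'
#' \code{sqrt(mean((est - ref)^2)) / sqrt(mean(ref^2))}: the RMS of the
#' estimate-minus-reference difference over the evaluated voxels, divided
#' by the RMS of the reference. Scale invariant: multiplying both inputs
#' by the same positive constant leaves it unchanged. When no mask is
#' supplied, all voxels/pixels are used.
#'
#' @param ref reference values (array, \code{VoxelVolume} or
#'   \code{ProjectionSet}); must not be all zero.
#' @param est estimate on the same grid.
#' @param mask optional logical mask or \code{VOIMask} restricting the
#'   evaluation.
#' @return nonnegative scalar (multiply by 100 for percent).
#' @export
nrmsd <- function(ref, est, mask = NULL) {
  r <- maskValues(ref, mask); e <- maskValues(est, mask)
  if (length(r) != length(e)) stop("ref and est must match in size")
  den <- sqrt(mean(r^2))
  if (den == 0) stop("undefined metric: reference is all zero")
  sqrt(mean((e - r)^2)) / den
}

#' Activity recovery
#'
#' Mean reconstructed activity over a VOI divided by the mean true
#' activity over the same VOI; below 1 for small objects due to
#' partial-volume effects.
#'
#' @param recon reconstructed \code{VoxelVolume} (or array).
#' @param truth true activity \code{VoxelVolume} (or array), same grid.
#' @param voi \code{VOIMask} (or logical array).
#' @return the AR ratio.
#' @export
activityRecovery <- function(recon, truth, voi) {
  den <- mean(maskValues(truth, voi))
  if (den <= 0) stop("undefined metric: zero mean true activity in VOI")
  mean(maskValues(recon, voi)) / den
}

#' Background noise
#'
#' Population standard deviation of voxel values over the background
#' mask.
#'
#' @param recon \code{VoxelVolume} or array.
#' @param bkg background \code{VOIMask} (>= 2 voxels).
#' @return STD over the background.
#' @export
noiseStd <- function(recon, bkg) {
  v <- maskValues(recon, bkg)
  if (length(v) < 2L) stop("undefined metric: background mask too small")
  sqrt(mean((v - mean(v))^2))  # population SD, per the formulaic reading
}

#' Contrast-to-noise ratio and relative measures
#'
#' \code{cnr}: (VOI mean - background mean) / background STD.
#' \code{rcnr}: CNR of a sparse-view reconstruction relative to the
#' full-view CNR, in percent. \code{rcr}: VOI mean of a sparse-view
#' reconstruction relative to the full-view VOI mean, in percent.
#'
#' @param recon \code{VoxelVolume} or array.
#' @param voi,bkg \code{VOIMask}s.
#' @return \code{cnr}: a real; \code{rcnr}/\code{rcr}: percent.
#' @export
cnr <- function(recon, voi, bkg) {
  s <- noiseStd(recon, bkg)
  if (s <= 0) stop("undefined metric: zero background STD")
  (mean(maskValues(recon, voi)) - mean(maskValues(recon, bkg))) / s
}

#' @rdname cnr
#' @param cnrSparse,cnrFull CNR of the sparse-view and full-view
#'   reconstructions.
#' @export
rcnr <- function(cnrSparse, cnrFull) {
  if (cnrFull == 0) stop("undefined metric: zero full-recon CNR")
  100 * cnrSparse / cnrFull
}

#' @rdname cnr
#' @param meanSparseVoi,meanFullVoi VOI means of the sparse-view and
#'   full-view reconstructions.
#' @export
rcr <- function(meanSparseVoi, meanFullVoi) {
  if (meanFullVoi == 0) stop("undefined metric: zero full-recon VOI mean")
  100 * meanSparseVoi / meanFullVoi
}

#' Noise versus mean activity recovery across iterations
#'
#' One point per stored OS-EM checkpoint: the background noise STD and
#' the unweighted mean AR across the supplied sphere VOIs, ordered by
#' iteration - the data behind noise-to-recovery trade-off curves.
#'
#' @param result a \code{ReconResult}.
#' @param truth true activity \code{VoxelVolume}.
#' @param vois list of sphere \code{VOIMask}s.
#' @param bkg background \code{VOIMask}.
#' @return data.frame(iteration, stdBkg, meanAR), iteration-ordered.
#' @export
noiseArCurve <- function(result, truth, vois, bkg) {
  if (!length(vois)) stop("argument error: empty VOI list")
  its <- sort(checkpointIterations(result))
  rows <- lapply(its, function(it) {
    vol <- checkpoint(result, it)
    ars <- vapply(vois, function(v) activityRecovery(vol, truth, v),
                  numeric(1))
    data.frame(iteration = it, stdBkg = noiseStd(vol, bkg),
               meanAR = mean(ars))
  })
  do.call(rbind, rows)
}

#' Assemble one metrics record
#'
#' A tidy row for results tables: metric name, value, VOI label, pipeline
#' label, down-sampling factor and iteration.
#'
#' @param metric one of NRMSD, AR, STD_BKG, CNR, RCR, RCNR.
#' @param value metric value (relative measures in percent).
#' @param voiLabel,pipeline,DF,iteration identifying labels.
#' @return one-row data.frame with the fixed column set.
#' @export
metricsRecord <- function(metric, value, voiLabel = NA_character_,
                          pipeline = NA_character_, DF = NA_integer_,
                          iteration = NA_integer_) {
  metric <- match.arg(metric,
                      c("NRMSD", "AR", "STD_BKG", "CNR", "RCR", "RCNR"))
  data.frame(metric = metric, value = value, voi_label = voiLabel,
             pipeline = pipeline, DF = DF, iteration = iteration,
             stringsAsFactors = FALSE)
}
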