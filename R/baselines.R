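## Comparison pipelines: angular linear interpolation of skipped views,
## and Bernoulli thinning of measured counts (emulating a shorter dwell
## time per view instead of skipped views).

#' Linear angular interpolation of skipped views
#'
#' Each skipped view is the pixelwise linear blend of its two nearest
#' measured neighbours in angle, with weights proportional to angular
#' proximity, wrapping around the 0/2 pi seam (views sample a full
#' circle).
#'
#' @param measured \code{ProjectionSet} of measured views (>= 2).
#' @param skippedAngles radians of the views to interpolate.
#' @param geom full \code{AcquisitionGeometry} the skipped angles belong
#'   to (supplies their radii); defaults to looking them up in the
#'   measured geometry's detector description with radii interpolated.
#' @return \code{ProjectionSet} with provenance \code{"interpolated"}.
#' @export
linInterpViews <- function(measured, skippedAngles, geom = NULL) {
  if (nViews(measured) < 2L)
    stop("argument error: need at least 2 measured views")
  aM <- viewAngles(measured)
  cts <- counts(measured)
  d12 <- dim(cts)[1:2]
  out <- array(0, c(d12, length(skippedAngles)))
  radii <- numeric(length(skippedAngles))
  for (k in seq_along(skippedAngles)) {
    th <- skippedAngles[k]
    ## circular distances to measured angles
    below <- aM[aM < th]
    above <- aM[aM > th]
    thLo <- if (length(below)) max(below) else max(aM) - 2 * pi
    thHi <- if (length(above)) min(above) else min(aM) + 2 * pi
    iLo <- which.min(abs(aM - (thLo %% (2 * pi))))
    iHi <- which.min(abs(aM - (thHi %% (2 * pi))))
    span <- thHi - thLo
    wHi <- (th - thLo) / span
    out[, , k] <- (1 - wHi) * cts[, , iLo] + wHi * cts[, , iHi]
    radii[k] <- (1 - wHi) * viewRadii(geometry(measured))[iLo] +
      wHi * viewRadii(geometry(measured))[iHi]
  }
  if (!is.null(geom)) {
    idx <- match(round(skippedAngles, 12), round(geom@angles, 12))
    if (!anyNA(idx)) radii <- geom@radii[idx]
  }
  og <- geometry(measured)
  ord <- order(skippedAngles)
  new("ProjectionSet", counts = out[, , ord, drop = FALSE],
      geom = new("AcquisitionGeometry", angles = skippedAngles[ord],
                 radii = radii[ord], nU = og@nU, nV = og@nV,
                 pixelMm = og@pixelMm),
      window = windowLabel(measured),
      provenance = rep("interpolated", length(skippedAngles)),
      dwellS = measured@dwellS)
}

#' Bernoulli thinning of projection counts
#'
#' Retains each recorded event independently with probability 1/DF,
#' implemented as a Binomial(k, 1/DF) draw per bin - distributionally
#' identical to per-event thinning. For Poisson(mu) input the output is
#' Poisson(mu/DF), emulating an acquisition with dwell time shortened by
#' DF. Thinned counts never exceed the originals; deterministic per seed.
#'
#' @param proj \code{ProjectionSet} with integer counts.
#' @param DF integer down-sampling factor >= 1 (1 is the identity).
#' @param seed integer seed.
#' @return thinned \code{ProjectionSet}.
#' @export
bernoulliThin <- function(proj, DF, seed = 1L) {
  DF <- as.integer(DF)
  if (DF < 1L) stop("DF must be >= 1")
  k <- counts(proj)
  if (max(abs(k - round(k))) > 1e-9)
    stop("input error: thinning is defined on integer event counts")
  if (DF == 1L) return(proj)
  thinned <- withLocalSeed(deriveSeed(seed, "thin"), {
    array(rbinom(length(k), size = as.integer(round(k)), prob = 1 / DF),
          dim(k))
  })
  projectionSet(thinned, geometry(proj), window = windowLabel(proj),
                provenance = provenance(proj), dwellS = proj@dwellS / DF)
}
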