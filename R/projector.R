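## Attenuated parallel-beam forward/back projector with depth-dependent
## Gaussian collimator response. Rotation-based: the volume is pushed onto
## the rotated frame of each view with a mass-preserving bilinear scatter
## (a sparse matrix), attenuated along the ray axis, blurred per
## constant-distance plane with a symmetric Gaussian, and summed toward the
## detector. The back projector applies the exact transpose of every step,
## so the pair is a matched adjoint to machine precision.

## Sparse push-rotation of an (nx, ny) slice by angle theta. Column j of
## the matrix distributes source voxel j bilinearly over its 4 nearest
## rotated grid neighbours (weights sum to 1; out-of-grid mass is dropped),
## so in-grid rotation conserves total counts exactly.
rotationPush <- function(theta, nx, ny) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  src <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  px <- src$i - cx; py <- src$j - cy
  u <- px * cos(theta) - py * sin(theta) + cx
  w <- px * sin(theta) + py * cos(theta) + cy
  i0 <- floor(u); j0 <- floor(w)
  fu <- u - i0; fw <- w - j0
  srcIdx <- rep(seq_len(nx * ny), 4L)
  ti <- c(i0, i0 + 1, i0, i0 + 1)
  tj <- c(j0, j0, j0 + 1, j0 + 1)
  wt <- c((1 - fu) * (1 - fw), fu * (1 - fw), (1 - fu) * fw, fu * fw)
  keep <- ti >= 1 & ti <= nx & tj >= 1 & tj <= ny & wt > 0
  Matrix::sparseMatrix(i = (ti[keep] - 1L) + (tj[keep] - 1L) * nx + 1L,
                       j = srcIdx[keep], x = wt[keep],
                       dims = c(nx * ny, nx * ny))
}

## Symmetric truncated-Gaussian convolution matrix (1D, zero padding). The
## kernel is normalized once by its full truncated sum, so the matrix is
## symmetric Toeplitz and hence self-adjoint; edge rows lose mass instead
## of being renormalized, which would break symmetry.
blurMatrix1D <- function(n, sigmaVox) {
  if (sigmaVox < 1e-3) return(NULL)
  h <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  off <- -h:h
  k <- exp(-off^2 / (2 * sigmaVox^2))
  k <- k / sum(k)
  rows <- integer(0); cols <- integer(0); xs <- numeric(0)
  for (t in seq_along(off)) {
    d <- off[t]
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    rows <- c(rows, i[ok]); cols <- c(cols, j[ok])
    xs <- c(xs, rep(k[t], sum(ok)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = xs, dims = c(n, n))
}

## Reverse cumulative sum along dim 2 of a 3D array:
## out[, w, ] = sum over w' >= w of a[, w', ].
revCumsumDim2 <- function(a) {
  ny <- dim(a)[2]
  if (ny > 1) for (w in (ny - 1):1) a[, w, ] <- a[, w, ] + a[, w + 1, ]
  a
}

## Build the per-view system model. Returns a closure-based operator list:
##   $fpView(X, v): (nx*ny) x nz activity matrix -> nx x nz expected counts
##   $bpView(Y, v): exact transpose
## X columns are z-slices in vec() order; the scalar `scale` (dwell *
## sensitivity * voxel volume in mL) is applied in both directions so the
## pair stays adjoint.
makeProjector <- function(geom, volDim, voxelMm, mu = NULL, psf = NULL,
                          dwellS = 1, sensitivity = 1) {
  nx <- volDim[1]; ny <- volDim[2]; nz <- volDim[3]
  if (nx != geom@nU || nz != geom@nV)
    stop("shape error: volume (", nx, ",", ny, ",", nz,
         ") does not match detector ", geom@nU, "x", geom@nV)
  if (abs(voxelMm - geom@pixelMm) > 1e-9)
    stop("shape error: voxel size must equal detector pixel size")
  muArr <- NULL
  if (!is.null(mu)) {
    if (!identical(dim(mu@values), as.integer(volDim)) &&
        !identical(dim(mu@values), volDim))
      stop("shape error: attenuation grid does not match activity grid")
    muArr <- mu@values
  }
  voxCm <- voxelMm / 10
  scale <- dwellS * sensitivity * (voxelMm / 10)^3  # voxel volume in mL
  cy <- (ny + 1) / 2
  nv <- length(geom@angles)

  rot <- lapply(geom@angles, rotationPush, nx = nx, ny = ny)

  ## per-view blur matrices, cached by (n, sigma) across views
  blurCache <- new.env(parent = emptyenv())
  getBlur <- function(n, sigmaVox) {
    key <- sprintf("%d_%.6f", n, sigmaVox)
    if (is.null(blurCache[[key]]))
      blurCache[[key]] <- blurMatrix1D(n, sigmaVox)
    blurCache[[key]]
  }
  blurs <- NULL
  if (!is.null(psf)) {
    blurs <- lapply(seq_len(nv), function(v) {
      lapply(seq_len(ny), function(w) {
        d <- max(0, geom@radii[v] - (w - cy) * voxelMm)
        sVox <- psfSigma(psf, d) / voxelMm
        list(u = getBlur(nx, sVox), z = getBlur(nz, sVox))
      })
    })
  }

  ## attenuation factor per view, cached when the total footprint is small
  attCache <- vector("list", nv)
  cacheAtt <- !is.null(muArr) &&
    (as.numeric(nx) * ny * nz * nv * 8 < 1.5e9)
  getAtt <- function(v) {
    if (is.null(muArr)) return(NULL)
    if (cacheAtt && !is.null(attCache[[v]])) return(attCache[[v]])
    mr <- as.matrix(rot[[v]] %*% matrix(muArr, nx * ny, nz))
    mra <- array(mr, c(nx, ny, nz))
    s <- revCumsumDim2(mra)
    att <- exp(-voxCm * (s - 0.5 * mra))
    att <- matrix(att, nx * ny, nz)
    if (cacheAtt) attCache[[v]] <<- att
    att
  }

  fpView <- function(X, v) {
    M <- as.matrix(rot[[v]] %*% X)
    att <- getAtt(v)
    if (!is.null(att)) M <- M * att
    arr <- array(M, c(nx, ny, nz))
    proj <- matrix(0, nx, nz)
    if (is.null(blurs)) {
      for (w in seq_len(ny)) proj <- proj + arr[, w, ]
    } else {
      bv <- blurs[[v]]
      for (w in seq_len(ny)) {
        plane <- arr[, w, , drop = TRUE]
        if (nz == 1L) plane <- matrix(plane, nx, 1)
        b <- bv[[w]]
        if (!is.null(b$u)) plane <- as.matrix(b$u %*% plane %*% b$z)
        proj <- proj + plane
      }
    }
    proj * scale
  }

  bpView <- function(Y, v) {
    arr <- array(0, c(nx, ny, nz))
    if (is.null(blurs)) {
      for (w in seq_len(ny)) arr[, w, ] <- Y
    } else {
      bv <- blurs[[v]]
      for (w in seq_len(ny)) {
        plane <- Y
        b <- bv[[w]]
        if (!is.null(b$u)) plane <- as.matrix(b$u %*% plane %*% b$z)
        arr[, w, ] <- plane
      }
    }
    M <- matrix(arr, nx * ny, nz)
    att <- getAtt(v)
    if (!is.null(att)) M <- M * att
    as.matrix(Matrix::crossprod(rot[[v]], M)) * scale
  }

  list(fpView = fpView, bpView = bpView, scale = scale,
       nx = nx, ny = ny, nz = nz, nViews = nv)
}

#' Forward project an activity volume
#'
#' Computes noiseless expected projection counts for every view of the
#' geometry: the activity is rotated into each view's frame, attenuated
#' voxelwise by \code{exp(-integral of mu dl)} along the ray from emission
#' point to detector (voxel-center sampling), blurred per constant-distance
#' plane by the depth-dependent Gaussian collimator response, and summed
#' along the ray axis. Expected counts scale as
#' \code{dwellS * sensitivity * voxel volume (mL) * activity (MBq/mL)}.
#'
#' @param vol activity \code{VoxelVolume} (MBq/mL); grid (nU, ny, nV) with
#'   voxel size equal to the detector pixel size.
#' @param geom \code{AcquisitionGeometry}.
#' @param mu attenuation \code{VoxelVolume} (1/cm) on the same grid, or
#'   NULL for no attenuation.
#' @param psf \code{PSFModel} or NULL for an ideal collimator.
#' @param dwellS acquisition seconds per view.
#' @param sensitivity detector sensitivity in counts per (MBq*s).
#' @return a \code{ProjectionSet} of noiseless expected counts
#'   (window \code{"photopeak"}, provenance \code{"measured"}).
#' @seealso [backProject()] for the exact adjoint.
#' @export
forwardProject <- function(vol, geom, mu = NULL, psf = NULL,
                           dwellS = 1, sensitivity = 1) {
  stopifnot(is(vol, "VoxelVolume"))
  if (dwellS <= 0 || sensitivity <= 0)
    stop("dwellS and sensitivity must be positive")
  P <- makeProjector(geom, dim(vol@values), vol@voxelMm, mu, psf,
                     dwellS, sensitivity)
  X <- matrix(vol@values, P$nx * P$ny, P$nz)
  out <- array(0, c(P$nx, P$nz, P$nViews))
  for (v in seq_len(P$nViews)) out[, , v] <- P$fpView(X, v)
  projectionSet(out, geom, window = "photopeak",
                provenance = "measured", dwellS = dwellS)
}

#' Back project a projection set
#'
#' Exact adjoint of [forwardProject()] under the same attenuation map, PSF
#' model and scaling, as required by EM-type reconstruction: for random x
#' and y, \code{<Ax, y> == <x, A'y>} to machine precision.
#'
#' @param proj a \code{ProjectionSet}.
#' @inheritParams forwardProject
#' @param voxelNy number of voxels along the volume y axis (defaults to
#'   nU, giving a square transaxial grid).
#' @return a \code{VoxelVolume} with role \code{"reconstruction"}.
#' @export
backProject <- function(proj, geom = geometry(proj), mu = NULL, psf = NULL,
                        dwellS = 1, sensitivity = 1, voxelNy = NULL) {
  stopifnot(is(proj, "ProjectionSet"))
  if (!identical(dim(proj@counts)[c(1, 2)],
                 c(geom@nU, geom@nV)) &&
      !all(dim(proj@counts)[c(1, 2)] == c(geom@nU, geom@nV)))
    stop("shape error: projection dims do not match geometry")
  if (dim(proj@counts)[3] != length(geom@angles))
    stop("shape error: view count mismatch")
  ny <- if (is.null(voxelNy)) geom@nU else as.integer(voxelNy)
  volDim <- c(geom@nU, ny, geom@nV)
  P <- makeProjector(geom, volDim, geom@pixelMm, mu, psf,
                     dwellS, sensitivity)
  acc <- matrix(0, P$nx * P$ny, P$nz)
  for (v in seq_len(P$nViews))
    acc <- acc + P$bpView(proj@counts[, , v], v)
  ## no clamping: the operator is exactly the transpose of forwardProject,
  ## and nonnegative inputs yield nonnegative outputs anyway
  voxelVolume(array(acc, volDim), geom@pixelMm, role = "reconstruction")
}
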