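## Per-scan coordinate network: a fully connected MLP mapping the 5D
## projection-pixel coordinate (x, y, sin theta, cos theta, r) to a count.
## Trained with Huber loss, Adam and a reduce-on-plateau scheduler on the
## measured views of one scan only; queried at the skipped gantry angles.
## The forward pass, backpropagation and the optimizer are implemented as
## plain BLAS-backed matrix code.

#' Huber loss
#'
#' \code{0.5 * a^2} for \code{|a| < delta}, else
#' \code{delta * (|a| - 0.5 * delta)}: quadratic near zero for strong
#' gradients, linear in the tails for robustness to the outliers typical
#' of low-count projection data. Continuously differentiable at
#' \code{|a| = delta}.
#'
#' @param a residual(s): predicted minus measured count.
#' @param delta positive transition threshold (default 1).
#' @return elementwise loss, same shape as \code{a}.
#' @examples
#' huberLoss(0.5)  # 0.125
#' huberLoss(2)    # 1.5
#' @export
huberLoss <- function(a, delta = 1) {
  if (delta <= 0) stop("delta must be positive")
  ifelse(abs(a) < delta, 0.5 * a^2, delta * (abs(a) - 0.5 * delta))
}

## d loss / d a
huberGrad <- function(a, delta = 1) {
  ifelse(abs(a) < delta, a, delta * sign(a))
}

#' Rescale trick: nearest-neighbour up- and down-scaling
#'
#' Before training, each measured view is upscaled by pixel duplication
#' (every source pixel fills its 2 x 2 block), so the network sees a finer
#' grid while the pixel-intensity multiset is preserved; after inference
#' the synthesized views are downscaled back by taking the top-left pixel
#' of each 2 x 2 block (the pre-defined selection rule), so
#' \code{rescaleDown(rescaleUp(x)) == x} exactly.
#'
#' @param view 2D numeric matrix (a single projection view).
#' @return \code{rescaleUp}: a matrix of twice the size per axis;
#'   \code{rescaleDown}: a matrix of half the size per axis.
#' @examples
#' rescaleUp(matrix(5))             # 2 x 2, all 5
#' rescaleDown(matrix(1:4, 2, 2))   # matrix(1)
#' @export
rescaleUp <- function(view) {
  view <- as.matrix(view)
  view[rep(seq_len(nrow(view)), each = 2L),
       rep(seq_len(ncol(view)), each = 2L), drop = FALSE]
}

#' @rdname rescaleUp
#' @export
rescaleDown <- function(view) {
  view <- as.matrix(view)
  if (nrow(view) %% 2L || ncol(view) %% 2L)
    stop("shape error: dimensions must be even")
  view[seq(1L, nrow(view), by = 2L), seq(1L, ncol(view), by = 2L),
       drop = FALSE]
}

#' Build the 5D coordinate set for a group of views
#'
#' One row per (pixel, view): pixel centers mapped per axis to
#' \code{[-1, 1]}, \code{sin} and \code{cos} of the view angle, and the
#' radial position divided by the maximum radius of the geometry (so a
#' circular orbit gives \code{rNorm == 1} for every row). Rows are ordered
#' pixel-column-major within view, views in the given order, matching
#' \code{as.vector()} of a (nU, nV, nViews) array.
#'
#' @param geom \code{AcquisitionGeometry} (supplies radii and the radius
#'   normalization).
#' @param angleSubset angles (radians) of the views to enumerate; must be
#'   a subset of \code{viewAngles(geom)}.
#' @param gridDim integer length-2 (nU, nV) pixel grid of each view; use
#'   twice the detector matrix when the rescale trick is on.
#' @return matrix with columns \code{x, y, sin, cos, r} and
#'   \code{prod(gridDim) * length(angleSubset)} rows.
#' @export
buildCoordinates <- function(geom, angleSubset, gridDim) {
  if (!length(angleSubset)) stop("argument error: empty angle subset")
  idx <- match(round(angleSubset, 12), round(geom@angles, 12))
  if (anyNA(idx))
    stop("argument error: angles not found in geometry")
  gridDim <- as.integer(gridDim)
  axisNorm <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  xs <- axisNorm(gridDim[1])
  ys <- axisNorm(gridDim[2])
  npix <- gridDim[1] * gridDim[2]
  xcol <- rep(xs, times = gridDim[2])
  ycol <- rep(ys, each = gridDim[1])
  rMax <- max(geom@radii)
  out <- matrix(0, npix * length(idx), 5L,
                dimnames = list(NULL, c("x", "y", "sin", "cos", "r")))
  for (k in seq_along(idx)) {
    th <- geom@angles[idx[k]]
    rows <- (k - 1L) * npix + seq_len(npix)
    out[rows, 1L] <- xcol
    out[rows, 2L] <- ycol
    out[rows, 3L] <- sin(th)
    out[rows, 4L] <- cos(th)
    out[rows, 5L] <- geom@radii[idx[k]] / rMax
  }
  out
}

## ---- MLP internals ------------------------------------------------------

## He-initialized fully connected net: sizes = c(5, hidden..., 1)
mlpInit <- function(hiddenLayers, hiddenUnits) {
  sizes <- c(5L, rep(as.integer(hiddenUnits), hiddenLayers), 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                           sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

## forward pass; returns activations for backprop when keep = TRUE.
## Hidden: ReLU. Output: softplus, so predicted counts are nonnegative.
mlpForward <- function(par, X, keep = FALSE) {
  L <- length(par$W)
  acts <- if (keep) vector("list", L + 1L)
  if (keep) acts[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% par$W[[l]]
    Z <- sweep(Z, 2L, par$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else softplus(Z)
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = as.numeric(A), acts = acts) else as.numeric(A)
}

## gradient of mean Huber loss wrt all parameters
mlpBackward <- function(par, fw, targets, delta) {
  L <- length(par$W)
  n <- length(targets)
  pred <- fw$out
  ## d mean-loss / d pred, then through softplus: sigma(z) = 1 - exp(-a)
  ## where a = softplus(z); use pred to recover sigmoid stably
  dL <- huberGrad(pred - targets, delta) / n
  sig <- 1 - exp(-pmax(pred, 1e-12))
  G <- matrix(dL * sig, n, 1L)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    A <- fw$acts[[l]]
    gW[[l]] <- crossprod(A, G)
    gb[[l]] <- colSums(G)
    if (l > 1L) {
      G <- G %*% t(par$W[[l]])
      G <- G * (fw$acts[[l]] > 0)  # ReLU mask
    }
  }
  list(W = gW, b = gb)
}

adamInit <- function(par) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero(par$W), vW = zero(par$W),
       mb = zero(par$b), vb = zero(par$b), t = 0L)
}

adamStep <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(par = par, state = state)
}

#' Training configuration for the coordinate network
#'
#' Defaults follow the per-scan training recipe: Huber delta 1, Adam with
#' initial learning rate 0.001 and a reduce-on-plateau scheduler (factor
#' 0.5, patience 10 epochs on validation loss), 200 epochs, batches of
#' 10,000 coordinates, a randomly selected 20 percent of pixel coordinates
#' held out as validation data, 12 hidden layers of 256 units, and the
#' rescale trick enabled.
#'
#' @param delta Huber transition threshold.
#' @param lr initial Adam learning rate.
#' @param epochs training epochs.
#' @param batchCoords coordinates per minibatch.
#' @param valFraction fraction of pixel coordinates held out for
#'   validation (excluded from gradient updates).
#' @param hiddenLayers,hiddenUnits architecture.
#' @param rescale apply the rescale trick.
#' @param schedFactor,schedPatience reduce-on-plateau settings.
#' @param minLr floor for the scheduled learning rate.
#' @return a validated \code{TrainConfig} list.
#' @export
trainConfig <- function(delta = 1, lr = 1e-3, epochs = 200L,
                        batchCoords = 10000L, valFraction = 0.2,
                        hiddenLayers = 12L, hiddenUnits = 256L,
                        rescale = TRUE, schedFactor = 0.5,
                        schedPatience = 10L, minLr = 1e-6) {
  if (delta <= 0) stop("delta must be positive")
  if (valFraction <= 0 || valFraction >= 1)
    stop("valFraction must be in (0, 1)")
  structure(list(delta = delta, lr = lr, epochs = as.integer(epochs),
                 batchCoords = as.integer(batchCoords),
                 valFraction = valFraction,
                 hiddenLayers = as.integer(hiddenLayers),
                 hiddenUnits = as.integer(hiddenUnits),
                 rescale = isTRUE(rescale),
                 schedFactor = schedFactor,
                 schedPatience = as.integer(schedPatience),
                 minLr = minLr),
            class = "TrainConfig")
}

#' Train a per-scan coordinate network on measured views
#'
#' Fits the MLP to the measured projection views of one scan: views are
#' optionally upscaled with the rescale trick, every pixel of every
#' measured view becomes one (coordinate, count) pair, a seeded 20 percent
#' of the pairs is held out as validation data (excluded from gradient
#' updates), and the mean Huber loss is minimized with Adam under a
#' reduce-on-plateau schedule. Targets are scaled by the 99.9th percentile
#' of the measured counts so the Huber threshold stays meaningful across
#' count levels; the scale is undone at inference. The returned model is
#' the epoch snapshot with the lowest validation loss. Deterministic for a
#' fixed seed.
#'
#' @param measured \code{ProjectionSet} of measured views (>= 2 views).
#' @param cfg a [trainConfig()].
#' @param seed integer seed for the split, the initialization and the
#'   batch shuffling.
#' @return a \code{SperfModel}; its \code{trainLog()} has one row per
#'   epoch (train loss, validation loss, learning rate).
#' @export
trainSperf <- function(measured, cfg = trainConfig(), seed = 1L) {
  stopifnot(is(measured, "ProjectionSet"))
  if (nViews(measured) < 2L)
    stop("insufficient data: need at least 2 measured views")
  geom <- geometry(measured)
  cts <- counts(measured)
  if (cfg$rescale) {
    up <- array(0, c(2L * dim(cts)[1], 2L * dim(cts)[2], dim(cts)[3]))
    for (v in seq_len(dim(cts)[3])) up[, , v] <- rescaleUp(cts[, , v])
    cts <- up
  }
  gridDim <- dim(cts)[1:2]
  coords <- buildCoordinates(geom, viewAngles(measured), gridDim)
  targets <- as.numeric(cts)
  tScale <- as.numeric(quantile(targets, 0.999, names = FALSE))
  if (tScale <= 0) tScale <- 1
  t <- targets / tScale
  n <- length(t)

  withLocalSeed(deriveSeed(seed, "split"), {
    valIdx <- sample.int(n, round(cfg$valFraction * n))
  })
  trainIdx <- setdiff(seq_len(n), valIdx)
  Xtr <- coords[trainIdx, , drop = FALSE]; ttr <- t[trainIdx]
  Xva <- coords[valIdx, , drop = FALSE]; tva <- t[valIdx]

  par <- withLocalSeed(deriveSeed(seed, "init"),
                       mlpInit(cfg$hiddenLayers, cfg$hiddenUnits))
  opt <- adamInit(par)
  lr <- cfg$lr
  best <- list(val = Inf, par = par)
  sinceBest <- 0L
  log <- data.frame(epoch = integer(), train = numeric(),
                    val = numeric(), lr = numeric())

  withLocalSeed(deriveSeed(seed, "shuffle"), {
    ntr <- length(ttr)
    nb <- max(1L, ceiling(ntr / cfg$batchCoords))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(ntr)
      epLoss <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[(((bi - 1L) * cfg$batchCoords + 1L)):
                      min(bi * cfg$batchCoords, ntr)]
        fw <- mlpForward(par, Xtr[rows, , drop = FALSE], keep = TRUE)
        loss <- mean(huberLoss(fw$out - ttr[rows], cfg$delta))
        if (!is.finite(loss)) stop("training diverged: non-finite loss")
        g <- mlpBackward(par, fw, ttr[rows], cfg$delta)
        st <- adamStep(par, g, opt, lr)
        par <- st$par; opt <- st$state
        epLoss <- epLoss + loss * length(rows)
      }
      predVa <- mlpForward(par, Xva)
      valLoss <- mean(huberLoss(predVa - tva, cfg$delta))
      if (!is.finite(valLoss)) stop("training diverged: non-finite loss")
      log <- rbind(log, data.frame(epoch = ep, train = epLoss / ntr,
                                   val = valLoss, lr = lr))
      if (valLoss < best$val - 1e-12) {
        best <- list(val = valLoss, par = par)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$schedPatience) {
          lr <- max(cfg$minLr, lr * cfg$schedFactor)
          sinceBest <- 0L
        }
      }
    }
  })

  new("SperfModel", weights = best$par$W, biases = best$par$b,
      normalization = list(rMax = max(geom@radii), targetScale = tScale,
                           gridDim = gridDim, rescale = cfg$rescale,
                           delta = cfg$delta),
      window = windowLabel(measured), trainLog = log)
}

#' Synthesize skipped projection views
#'
#' Queries a trained model at every pixel coordinate of the skipped gantry
#' angles and assembles the predictions into projection views; when the
#' model was trained with the rescale trick, predictions are made on the
#' doubled grid and downscaled back. Outputs are nonnegative by the output
#' activation.
#'
#' @param model a trained \code{SperfModel}.
#' @param geom the full \code{AcquisitionGeometry} (same normalization as
#'   at training).
#' @param skippedAngles angles (radians, within \code{[0, 2*pi)}) to
#'   synthesize; must be angles of \code{geom}.
#' @param dwellS dwell time tag for the output set.
#' @return \code{ProjectionSet} with provenance \code{"synthesized"}; an
#'   empty angle list returns a zero-view set.
#' @export
synthesizeViews <- function(model, geom, skippedAngles,
                            dwellS = 1) {
  stopifnot(is(model, "SperfModel"))
  if (length(skippedAngles) &&
      (any(skippedAngles < 0) || any(skippedAngles >= 2 * pi)))
    stop("argument error: angles must lie in [0, 2*pi)")
  nu <- geom@nU; nvx <- geom@nV
  if (!length(skippedAngles)) {
    return(new("ProjectionSet",
               counts = array(0, c(nu, nvx, 0L)),
               geom = geometrySubset(geom, integer(0)),
               window = model@window, provenance = character(0),
               dwellS = dwellS))
  }
  gridDim <- model@normalization$gridDim
  coords <- buildCoordinates(geom, skippedAngles, gridDim)
  par <- list(W = model@weights, b = model@biases)
  pred <- mlpForward(par, coords) * model@normalization$targetScale
  arr <- array(pred, c(gridDim[1], gridDim[2], length(skippedAngles)))
  out <- array(0, c(nu, nvx, length(skippedAngles)))
  for (v in seq_len(length(skippedAngles)))
    out[, , v] <- if (model@normalization$rescale)
      rescaleDown(arr[, , v]) else arr[, , v]
  out[out < 0] <- 0
  idx <- match(round(skippedAngles, 12), round(geom@angles, 12))
  projectionSet(out, geometrySubset(geom, idx), window = model@window,
                provenance = "synthesized", dwellS = dwellS)
}

#' Merge measured and synthesized views into a full set
#'
#' Interleaves two projection sets with disjoint angle sets into one set
#' sorted by angle; measured views pass through bit-identically and every
#' view keeps its provenance flag.
#'
#' @param measured,synthesized \code{ProjectionSet}s with the same window
#'   and pixel grid and disjoint angles.
#' @return combined \code{ProjectionSet}.
#' @export
mergeViews <- function(measured, synthesized) {
  if (nViews(synthesized) == 0L) return(measured)
  if (measured@window != synthesized@window)
    stop("merge error: window labels differ")
  if (!all(dim(measured@counts)[1:2] == dim(synthesized@counts)[1:2]))
    stop("merge error: pixel grids differ")
  aM <- viewAngles(measured); aS <- viewAngles(synthesized)
  if (length(intersect(round(aM, 12), round(aS, 12))))
    stop("merge error: overlapping angles")
  angles <- c(aM, aS)
  ord <- order(angles)
  cts <- array(0, c(dim(measured@counts)[1:2], length(angles)))
  cts[, , seq_along(aM)] <- measured@counts
  if (length(aS)) cts[, , length(aM) + seq_along(aS)] <- synthesized@counts
  cts <- cts[, , ord, drop = FALSE]
  geom <- new("AcquisitionGeometry",
              angles = angles[ord],
              radii = c(viewRadii(geometry(measured)),
                        viewRadii(geometry(synthesized)))[ord],
              nU = measured@geom@nU, nV = measured@geom@nV,
              pixelMm = measured@geom@pixelMm)
  projectionSet(cts, geom, window = measured@window,
                provenance = c(measured@provenance,
                               synthesized@provenance)[ord],
                dwellS = measured@dwellS)
}
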