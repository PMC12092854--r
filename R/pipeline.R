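## End-to-end orchestration of the four data-processing pipelines (Full,
## Partial, LinInt, SpeRF) plus optional Bernoulli thinning, from a single
## validated config with one master seed.

pipelineDefaults <- function() {
  list(
    phantom = list(n_xy = 128L, n_z = 48L, voxel_mm = 4.8,
                   body_axes_mm = c(300, 220), body_axial_mm = 200,
                   background_conc = 0.035, sphere_conc = 0.22,
                   sphere_volumes_ml = c(2, 4, 8, 16, 30, 114),
                   sphere_ring_mm = 65, mu_body = 0.135),
    geometry = list(n_views = 120L, orbit = "circular", radius_mm = 250,
                    a_mm = 300, b_mm = 200),
    psf = list(enabled = TRUE, sigma0_mm = 2, slope_mm_per_mm = 0.02),
    acquisition = list(dwell_s = 196, sensitivity_cps_per_mbq = 5,
                       scatter_fraction = 0.3, scatter_sigma_mm = 30),
    windows = list(photopeak_pct = 20, scatter_pct = 10, peak_kev = 208),
    sperf = list(delta = 1, lr = 1e-3, epochs = 200L,
                 batch_coords = 10000L, val_fraction = 0.2,
                 hidden_layers = 12L, hidden_units = 256L,
                 rescale = TRUE),
    recon = list(n_subsets = 6L, n_iters = 16L, epsilon = 1e-8,
                 save_every = 4L),
    experiment = list(df_list = 4L,
                      pipelines = c("Full", "Partial", "LinInt", "SpeRF"),
                      bertin = FALSE, seed = 1L)
  )
}

mergeChecked <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      mergeChecked(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Validate and normalize an experiment config
#'
#' Merges a user config (YAML file path or list) into the package
#' defaults, rejecting unknown keys with their field path, and resolves
#' derived units: energy-window widths in keV from their percentages of
#' the photopeak energy (20 percent at 208 keV gives 41.6 keV). When
#' \code{echoTo} is given, the effective config is written beside the
#' results.
#'
#' @param config YAML file path, a list, or NULL for all defaults.
#' @param echoTo optional path to write the effective config to (YAML).
#' @return the normalized config list with derived \code{windows$
#'   photopeak_kev} and \code{windows$scatter_kev}.
#' @export
validateConfig <- function(config = NULL, echoTo = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) user <- list()
  cfg <- mergeChecked(pipelineDefaults(), user)
  cfg$windows$photopeak_kev <-
    cfg$windows$photopeak_pct / 100 * cfg$windows$peak_kev
  cfg$windows$scatter_kev <-
    cfg$windows$scatter_pct / 100 * cfg$windows$peak_kev
  bad <- setdiff(cfg$experiment$pipelines,
                 c("Full", "Partial", "LinInt", "SpeRF"))
  if (length(bad))
    stop("config error: unknown pipeline(s): ", paste(bad, collapse = ", "))
  if (any(cfg$geometry$n_views %% cfg$experiment$df_list != 0))
    stop("config error: every DF must divide n_views")
  if (!is.null(echoTo)) yaml::write_yaml(cfg, echoTo)
  cfg
}

#' Desk-scale study configuration
#'
#' The reduced configuration used for CPU-scale end-to-end studies: a
#' 64 x 64 x 32 phantom grid at 4.8 mm voxels (140 mm axial body), 60
#' views, a 4 x 64 coordinate network trained for 50 epochs with batches
#' of 2048 coordinates (keeping the optimizer step budget comparable to
#' the full-scale recipe), and the standard OS-EM settings. Phantom
#' concentrations, windows and all physics parameters keep their
#' full-scale defaults.
#'
#' @param DF down-sampling factor(s) to study.
#' @param seed master seed.
#' @param pipelines pipelines to build.
#' @param bertin include the Bernoulli-thinning pipeline.
#' @return config list for [runExperiment()].
#' @export
scaledStudyConfig <- function(DF = 4L, seed = 1L,
                              pipelines = c("Full", "Partial", "LinInt",
                                            "SpeRF"),
                              bertin = FALSE) {
  list(
    phantom = list(n_xy = 64L, n_z = 32L, voxel_mm = 4.8,
                   body_axial_mm = 140),
    geometry = list(n_views = 60L),
    sperf = list(epochs = 50L, hidden_layers = 4L, hidden_units = 64L,
                 batch_coords = 2048L),
    experiment = list(df_list = as.integer(DF), seed = as.integer(seed),
                      pipelines = pipelines, bertin = bertin)
  )
}

## largest divisor of n that is <= target (subset count for short sets)
divisorAtMost <- function(n, target) {
  for (d in seq(min(target, n), 1L)) if (n %% d == 0L) return(as.integer(d))
  1L
}

#' Run the sparse-view experiment end to end
#'
#' Simulates (or accepts) a multi-window phantom acquisition, builds the
#' requested data-processing pipelines at each down-sampling factor -
#' Full (all views measured), Partial (only the measured subset), LinInt
#' (skipped views linearly interpolated), SpeRF (skipped views predicted
#' by per-scan photopeak and scatter-window coordinate models) and
#' optionally BerTin (all views Bernoulli-thinned) - reconstructs each
#' with the same OS-EM settings, and evaluates projection NRMSD and the
#' reconstruction metrics against the known truth.
#'
#' Scatter handling mirrors the two-model design: at measured angles the
#' TEW estimate comes from the measured scatter windows; at skipped
#' angles it comes from the second (scatter-window) coordinate model for
#' SpeRF and from angular interpolation for LinInt, with the synthesized
#' scatter sum split equally between the two windows before TEW (which
#' makes the estimate the synthesized sum itself).
#'
#' @param config config accepted by [validateConfig()].
#' @param outDir optional artifact directory; when given, reconstructions
#'   (NIfTI), metrics (CSV) and a JSON manifest (seed, config) are
#'   written there.
#' @param verbose print stage progress.
#' @return list with elements \code{config}, \code{phantom}, \code{geom},
#'   \code{sim} (measured window sets), \code{full} (ReconResult),
#'   \code{perDF} (per-DF list of pipeline results incl. models and
#'   synthesized sets), and \code{metrics} (tidy data.frame of
#'   \code{metricsRecord} rows).
#' @export
runExperiment <- function(config = NULL, outDir = NULL, verbose = FALSE) {
  cfg <- validateConfig(config)
  say <- function(...) if (verbose) message(...)
  seed <- cfg$experiment$seed

  ph <- cfg$phantom
  spec <- phantomSpec(nXY = ph$n_xy, nZ = ph$n_z, voxelMm = ph$voxel_mm,
                      bodyAxesMm = ph$body_axes_mm,
                      bodyAxialMm = ph$body_axial_mm,
                      backgroundConc = ph$background_conc,
                      sphereVolumesMl = ph$sphere_volumes_ml,
                      sphereConc = ph$sphere_conc,
                      sphereRingMm = ph$sphere_ring_mm,
                      muBody = ph$mu_body)
  phant <- makePhantom(spec)
  geom <- makeOrbit(cfg$geometry$n_views, cfg$geometry$orbit,
                    radiusMm = cfg$geometry$radius_mm,
                    aMm = cfg$geometry$a_mm, bMm = cfg$geometry$b_mm,
                    nU = ph$n_xy, nV = ph$n_z, pixelMm = ph$voxel_mm)
  psf <- if (isTRUE(cfg$psf$enabled))
    psfModel(cfg$psf$sigma0_mm, cfg$psf$slope_mm_per_mm) else NULL
  acq <- cfg$acquisition

  say("simulating acquisition (", nViews(geom), " views)")
  sim <- simulateAcquisition(phant$activity, phant$mu, geom, psf,
                             dwellS = acq$dwell_s,
                             sensitivity = acq$sensitivity_cps_per_mbq,
                             scatterFraction = acq$scatter_fraction,
                             scatterSigmaMm = acq$scatter_sigma_mm,
                             seed = deriveSeed(seed, "simulate"))
  scatSum <- scatterSum(sim$scatter_lower, sim$scatter_upper)
  tewFull <- tewScatterEstimate(sim$scatter_lower, sim$scatter_upper,
                                wLowKeV = cfg$windows$scatter_kev,
                                wUpKeV = cfg$windows$scatter_kev,
                                wPeakKeV = cfg$windows$photopeak_kev)
  rc <- cfg$recon
  reconOf <- function(projSet, scatSet, label) {
    nv <- nViews(projSet)
    c2 <- reconConfig(divisorAtMost(nv, rc$n_subsets), rc$n_iters,
                      rc$epsilon, rc$save_every)
    say("reconstructing ", label, " (", nv, " views, ",
        c2$nSubsets, " subsets)")
    osem(projSet, scatSet, geometry(projSet), phant$mu, psf, c2,
         dwellS = acq$dwell_s, sensitivity = acq$sensitivity_cps_per_mbq)
  }
  finalVol <- function(rr) checkpoint(rr, max(checkpointIterations(rr)))

  metrics <- list()
  addRec <- function(...) metrics[[length(metrics) + 1L]] <<-
    metricsRecord(...)
  sphereVois <- phant$vois[grep("^sphere", names(phant$vois))]
  bkg <- phant$vois$BKG

  reconMetrics <- function(rr, pipeline, DF, fullVol = NULL) {
    vol <- finalVol(rr)
    it <- max(checkpointIterations(rr))
    for (nm in names(sphereVois)) {
      addRec("AR", activityRecovery(vol, phant$activity, sphereVois[[nm]]),
             nm, pipeline, DF, it)
      addRec("CNR", cnr(vol, sphereVois[[nm]], bkg), nm, pipeline, DF, it)
      if (!is.null(fullVol)) {
        addRec("RCR", rcr(mean(maskValues(vol, sphereVois[[nm]])),
                          mean(maskValues(fullVol, sphereVois[[nm]]))),
               nm, pipeline, DF, it)
        addRec("RCNR", rcnr(cnr(vol, sphereVois[[nm]], bkg),
                            cnr(fullVol, sphereVois[[nm]], bkg)),
               nm, pipeline, DF, it)
      }
    }
    addRec("STD_BKG", noiseStd(vol, bkg), "BKG", pipeline, DF, it)
    vol
  }

  wantFull <- "Full" %in% cfg$experiment$pipelines
  full <- NULL; fullVol <- NULL
  if (wantFull) {
    full <- reconOf(sim$photopeak, tewFull, "Full")
    fullVol <- reconMetrics(full, "Full", 1L)
  }

  scfg <- trainConfig(delta = cfg$sperf$delta, lr = cfg$sperf$lr,
                      epochs = cfg$sperf$epochs,
                      batchCoords = cfg$sperf$batch_coords,
                      valFraction = cfg$sperf$val_fraction,
                      hiddenLayers = cfg$sperf$hidden_layers,
                      hiddenUnits = cfg$sperf$hidden_units,
                      rescale = cfg$sperf$rescale)

  perDF <- list()
  for (DF in cfg$experiment$df_list) {
    say("DF = ", DF)
    res <- list()
    down <- downsampleViews(sim$photopeak, DF)
    keptScat <- downsampleViews(scatSum, DF)$kept
    keptTew <- downsampleViews(tewFull, DF)$kept
    skippedAngles <- down$skippedAngles
    measPhoto <- down$kept
    skippedRef <- projectionSet(
      sim$photopeak@counts[, , down$skippedIdx, drop = FALSE],
      geometrySubset(geom, down$skippedIdx),
      window = "photopeak", dwellS = acq$dwell_s)
    res$measured <- measPhoto
    res$skippedRef <- skippedRef

    if ("Partial" %in% cfg$experiment$pipelines) {
      rr <- if (DF == 1L && wantFull) full
            else reconOf(measPhoto, keptTew, paste0("Partial DF", DF))
      res$partial <- rr
      reconMetrics(rr, "Partial", DF, fullVol)
    }
    if ("LinInt" %in% cfg$experiment$pipelines && DF > 1L) {
      li <- linInterpViews(measPhoto, skippedAngles, geom)
      liScat <- linInterpViews(keptScat, skippedAngles, geom)
      res$linint <- li
      addRec("NRMSD", nrmsd(skippedRef@counts, li@counts),
             "projections", "LinInt", DF, NA_integer_)
      mergedLi <- mergeViews(measPhoto, li)
      mergedLiScat <- mergeViews(keptTew, liScat)
      rr <- reconOf(mergedLi, mergedLiScat, paste0("LinInt DF", DF))
      res$linintRecon <- rr
      reconMetrics(rr, "LinInt", DF, fullVol)
    }
    if ("SpeRF" %in% cfg$experiment$pipelines && DF > 1L) {
      say("training photopeak model")
      mPhoto <- trainSperf(measPhoto, scfg,
                           seed = deriveSeed(seed, 7L + DF))
      say("training scatter model")
      mScat <- trainSperf(keptScat, scfg,
                          seed = deriveSeed(seed, 23L + DF))
      synPhoto <- synthesizeViews(mPhoto, geom, skippedAngles,
                                  dwellS = acq$dwell_s)
      synScat <- synthesizeViews(mScat, geom, skippedAngles,
                                 dwellS = acq$dwell_s)
      res$modelPhotopeak <- mPhoto
      res$modelScatter <- mScat
      res$sperf <- synPhoto
      addRec("NRMSD", nrmsd(skippedRef@counts, synPhoto@counts),
             "projections", "SpeRF", DF, NA_integer_)
      merged <- mergeViews(measPhoto, synPhoto)
      ## synthesized scatter_sum split equally across the two windows
      ## collapses back to the sum through the TEW formula
      mergedScat <- mergeViews(keptTew, synScat)
      rr <- reconOf(merged, mergedScat, paste0("SpeRF DF", DF))
      res$sperfRecon <- rr
      reconMetrics(rr, "SpeRF", DF, fullVol)
    }
    if (isTRUE(cfg$experiment$bertin) && DF > 1L) {
      thin <- bernoulliThin(sim$photopeak, DF,
                            seed = deriveSeed(seed, 41L + DF))
      thinLo <- bernoulliThin(sim$scatter_lower, DF,
                              seed = deriveSeed(seed, 43L + DF))
      thinUp <- bernoulliThin(sim$scatter_upper, DF,
                              seed = deriveSeed(seed, 47L + DF))
      thinTew <- tewScatterEstimate(thinLo, thinUp,
                                    wLowKeV = cfg$windows$scatter_kev,
                                    wUpKeV = cfg$windows$scatter_kev,
                                    wPeakKeV = cfg$windows$photopeak_kev)
      rr <- reconOf(thin, thinTew, paste0("BerTin DF", DF))
      res$bertin <- rr
      reconMetrics(rr, "BerTin", DF, fullVol)
    }
    perDF[[as.character(DF)]] <- res
  }

  metricsTab <- do.call(rbind, metrics)
  out <- list(config = cfg, phantom = phant, geom = geom, sim = sim,
              full = full, perDF = perDF, metrics = metricsTab)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metricsTab, file.path(outDir, "metrics.csv"),
              row.names = FALSE)
    if (!is.null(fullVol))
      writeVolume(fullVol, file.path(outDir, "recon_full.nii.gz"))
    for (df in names(perDF)) {
      for (nm in intersect(c("partial", "linintRecon", "sperfRecon",
                             "bertin"), names(perDF[[df]]))) {
        rr <- perDF[[df]][[nm]]
        writeVolume(finalVol(rr),
                    file.path(outDir,
                              sprintf("recon_%s_df%s.nii.gz", nm, df)))
      }
    }
    jsonlite::write_json(
      list(seed = seed, config = cfg,
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(cfg, file.path(outDir, "config_effective.yaml"))
  }
  out
}
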