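# Metric identities and hand-computed oracle fixtures.

test_that("NRMSD identities hold", {
  set.seed(2)
  ref <- array(runif(5 * 5 * 4, 1, 10), c(5, 5, 4))
  expect_equal(nrmsd(ref, ref), 0)
  expect_equal(nrmsd(ref, ref * 0), 1)
  expect_equal(nrmsd(ref, 1.5 * ref), 0.5)
  # scale invariance
  est <- ref + array(rnorm(100), dim(ref))
  expect_equal(nrmsd(3.7 * ref, 3.7 * est), nrmsd(ref, est))
  expect_error(nrmsd(ref * 0, ref), "undefined metric")
  # masked evaluation restricts to the mask
  mask <- array(FALSE, dim(ref)); mask[1:2, 1, 1] <- TRUE
  est2 <- ref; est2[1, 1, 1] <- ref[1, 1, 1] + 1
  manual <- sqrt(mean((est2[mask] - ref[mask])^2)) / sqrt(mean(ref[mask]^2))
  expect_equal(nrmsd(ref, est2, mask), manual)
})

test_that("AR, STD, CNR, RCR and RCNR match hand-computed fixtures", {
  dims <- c(5, 2, 1)
  truth <- array(0, dims); recon <- array(0, dims)
  voi <- array(FALSE, dims); bkg <- array(FALSE, dims)
  # 3-voxel VOI: truth {2,2,2}, recon {1,2,3} -> AR = 1
  voi[1:3, 1, 1] <- TRUE
  truth[1:3, 1, 1] <- 2; recon[1:3, 1, 1] <- c(1, 2, 3)
  expect_equal(activityRecovery(recon, truth, voi), 1)
  expect_equal(activityRecovery(0.8 * truth, truth, voi), 0.8)
  expect_equal(activityRecovery(truth, truth, voi), 1)

  # background {1,3}: population STD = 1
  bkg[4:5, 1, 1] <- TRUE
  recon[4:5, 1, 1] <- c(1, 3)
  expect_equal(noiseStd(recon, bkg), 1)
  expect_equal(noiseStd(recon * 4, bkg), 4)          # |c| scaling
  expect_equal(noiseStd(array(5, dims), bkg), 0)     # constant -> 0

  # CNR: VOI mean 2, BKG mean 2, STD 1 -> 0
  expect_equal(cnr(recon, voi, bkg), 0)
  # VOI mean 12, BKG mean 2, STD 5 -> 2
  r2 <- recon; r2[1:3, 1, 1] <- 12; r2[4:5, 1, 1] <- c(2 - 5, 2 + 5)
  m <- mean(r2[bkg]); s <- sqrt(mean((r2[bkg] - m)^2))
  expect_equal(s, 5); expect_equal(m, 2)
  expect_equal(cnr(r2, voi, bkg), 2)

  # relatives: self-comparison gives 100%
  expect_equal(rcr(mean(r2[voi]), mean(r2[voi])), 100)
  expect_equal(rcnr(cnr(r2, voi, bkg), cnr(r2, voi, bkg)), 100)
  expect_equal(rcr(6, 12), 50)
  expect_error(rcr(1, 0), "undefined metric")
  expect_error(cnr(array(1, dims), voi, bkg), "undefined metric")

  # independent spreadsheet-style recomputation on a random 10-voxel mask
  set.seed(77)
  vol <- array(runif(64, 1, 9), c(4, 4, 4))
  tru <- array(runif(64, 1, 9), c(4, 4, 4))
  m10 <- array(FALSE, c(4, 4, 4)); m10[sample(64, 10)] <- TRUE
  b10 <- array(FALSE, c(4, 4, 4)); b10[sample(which(!m10), 10)] <- TRUE
  expect_equal(activityRecovery(vol, tru, m10),
               sum(vol[m10]) / 10 / (sum(tru[m10]) / 10))
  expect_equal(noiseStd(vol, b10),
               sqrt(sum((vol[b10] - sum(vol[b10]) / 10)^2) / 10))
  expect_equal(cnr(vol, m10, b10),
               (mean(vol[m10]) - mean(vol[b10])) / noiseStd(vol, b10))
})

test_that("noise-AR curves are iteration-ordered with the expected shape", {
  g <- smallGeom(6, 15, 5)
  act <- circleActivity(15, 5, seed = 12)
  noiseless <- forwardProject(act, g, dwellS = 100, sensitivity = 10)
  set.seed(4)
  noisy <- projectionSet(array(rpois(length(counts(noiseless)),
                                     counts(noiseless)),
                               dim(counts(noiseless))), g)
  rr <- osem(noisy, cfg = reconConfig(2, 8, 1e-9, 2),
             dwellS = 100, sensitivity = 10)
  voiA <- array(FALSE, c(15, 15, 5)); voiA[7:9, 7:9, 3] <- TRUE
  bkgA <- array(FALSE, c(15, 15, 5)); bkgA[4:6, 4:6, 2:4] <- TRUE
  curve <- noiseArCurve(rr, act, list(voiMask(voiA, "voi")),
                        voiMask(bkgA, "BKG"))
  expect_equal(curve$iteration, c(2, 4, 6, 8))
  # background noise grows with OS-EM iterations on noisy data
  expect_true(all(diff(curve$stdBkg) > -1e-6 * curve$stdBkg[1]))
  expect_error(noiseArCurve(rr, act, list(), voiMask(bkgA, "BKG")),
               "argument error")

  # perfect reconstruction gives AR = 1 and truth's own background STD
  perfect <- new("ReconResult",
                 volumes = list("1" = act),
                 config = list(), provenance = "measured")
  c2 <- noiseArCurve(perfect, act, list(voiMask(voiA, "voi")),
                     voiMask(bkgA, "BKG"))
  expect_equal(c2$meanAR, 1)
  expect_equal(c2$stdBkg, noiseStd(act, voiMask(bkgA, "BKG")))
})

test_that("metrics records carry the fixed column set", {
  r <- metricsRecord("AR", 0.93, "sphere_114mL", "SpeRF", 4L, 16L)
  expect_equal(names(r), c("metric", "value", "voi_label", "pipeline",
                           "DF", "iteration"))
  expect_error(metricsRecord("XYZ", 1), "arg")
})
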