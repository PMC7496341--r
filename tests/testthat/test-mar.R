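# One shared acquisition set for the image-domain MAR checks: a seeded
# phantom instance at the scaled-study geometry, with its metal-free twin
# acquired under identical noise.
marFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pre <- studyPreset("scaled")
    g <- pre$geometry
    sp <- rebinSpectrum(loadSpectrum(), pre$spectrumBin)
    tabs <- attenuationTables()
    lf <- sampleLumpField(1)
    ph <- buildPhantom(insetAngle = 0.6, signalPresent = TRUE,
                       signalAmplitude = 1.03, lumpField = lf)
    phFree <- ph
    phFree@disks <- ph@disks[ph@disks$material != "iron", ]
    sim <- function(p, I0, seed = 77L) {
      mats <- materialLineIntegrals(p, g, 256L, 1)
      countsToLogSinogram(detectCounts(mats, sp, tabs, I0 = I0,
                                       s0 = 1e-6 * I0, readoutSigma = 5,
                                       seed = seed))
    }
    thr <- calibrateThresholds(pre)
    cache <<- list(pre = pre, g = g, ph = ph, phFree = phFree, sim = sim,
                   thr = thr, muEff = muWaterEffective(sp))
    cache
  }
})

test_that("sinogram segmentation obeys its threshold algebra", {
  fx <- marFixture()
  ls <- fx$sim(fx$ph, 1e6)
  expect_false(any(segmentSinogramMetal(ls, Inf)))
  expect_true(all(segmentSinogramMetal(ls, -Inf)))
  low <- segmentSinogramMetal(ls, max(sinogramValues(ls)) + 1)
  expect_false(any(low))
  # calibrated threshold flags bins inside the analytic iron trace only
  mask <- segmentSinogramMetal(ls, fx$thr$mar1)
  trace <- analyticIronTrace(fx$ph, fx$g) > 0
  expect_gt(mean(mask), 0)
  expect_gt(mean(trace[mask]), 0.99)  # essentially no false positives
})

test_that("inpainting bridges masked runs linearly and conserves the rest", {
  g <- tinyGeometry(65L)
  vals <- matrix(rep(seq_len(65), each = 180), 180, 65)
  vals[] <- 0
  vals[1, ] <- c(rep(0, 30), 99, rep(4, 34))          # worked example rows
  ls <- new("LogSinogram", values = vals, I0 = 1e6, s0 = 0, geometry = g)
  # single masked bin between neighbours 0 and 4 -> mean 2
  mask <- matrix(FALSE, 180, 65); mask[1, 31] <- TRUE
  out <- inpaintTrace(ls, mask)
  expect_equal(sinogramValues(out)[1, 31], 2)
  masked <- 1 + (31 - 1) * 180   # column-major index of bin (1, 31)
  expect_identical(sinogramValues(out)[-masked], vals[-masked])
  # a run of three between 0 and 4 -> the ramp 1, 2, 3
  vals2 <- matrix(0, 180, 65); vals2[2, 34] <- 4
  vals2[2, 30:33] <- c(0, 7, 7, 7)
  ls2 <- new("LogSinogram", values = vals2, I0 = 1e6, s0 = 0, geometry = g)
  mask2 <- matrix(FALSE, 180, 65); mask2[2, 31:33] <- TRUE
  out2 <- sinogramValues(inpaintTrace(ls2, mask2))
  expect_equal(out2[2, 31:33], c(1, 2, 3))
  # runs touching the detector edge copy the nearest unmasked value
  mask3 <- matrix(FALSE, 180, 65); mask3[3, 1:5] <- TRUE
  vals3 <- matrix(5, 180, 65)
  ls3 <- new("LogSinogram", values = vals3, I0 = 1e6, s0 = 0, geometry = g)
  expect_equal(sinogramValues(inpaintTrace(ls3, mask3))[3, 1:5],
               rep(5, 5))
  # empty mask is the identity
  expect_identical(sinogramValues(inpaintTrace(ls, matrix(FALSE, 180, 65))),
                   vals)
  # unmasked bins are bit-identical after inpainting (conservation)
  set.seed(3)
  noisy <- matrix(rnorm(180 * 65), 180, 65)
  lsn <- new("LogSinogram", values = noisy, I0 = 1e6, s0 = 0, geometry = g)
  mk <- matrix(runif(180 * 65) < 0.2, 180, 65)
  mk[, 33] <- FALSE   # keep one bin per view unmasked
  outn <- sinogramValues(inpaintTrace(lsn, mk))
  expect_identical(outn[!mk], noisy[!mk])
  # a fully masked view is a hard error
  mkAll <- mk; mkAll[4, ] <- TRUE
  expect_error(inpaintTrace(lsn, mkAll), "fully masked")
})

test_that("MAR 1 reduces streak energy at calibration and no-ops when the
           threshold is never reached", {
  fx <- marFixture()
  ls <- fx$sim(fx$ph, 1e6)
  lsFree <- fx$sim(fx$phFree, 1e6)
  ref <- pixels(fbp(lsFree, 256L))
  imgF <- fbp(ls, 256L)
  img1 <- mar1(ls, fx$thr$mar1, 256L, fbpImage = imgF)
  ironPx <- rasterizePhantom(fx$ph, 256L, 26)$channels$iron > 0
  streak <- function(img) {
    d <- (pixels(img) - ref)[!ironPx]
    sqrt(mean(d^2))
  }
  expect_lt(streak(img1), streak(imgF))
  # threshold above every value: output identical to plain FBP
  high <- mar1(ls, max(sinogramValues(ls)) + 1, 256L)
  expect_equal(pixels(high), pixels(imgF), tolerance = 1e-12)
  # metal-free phantom at calibration: calibrated threshold fires nowhere
  expect_false(any(segmentSinogramMetal(lsFree, fx$thr$mar1)))
})

test_that("MAR 1's mask empties at 1% of the calibration dose", {
  fx <- marFixture()
  ls4 <- fx$sim(fx$ph, 1e4)
  mask <- segmentSinogramMetal(ls4, fx$thr$mar1)
  expect_false(any(mask))
  img1 <- mar1(ls4, fx$thr$mar1, 256L)
  expect_equal(pixels(img1), pixels(fbp(ls4, 256L)), tolerance = 1e-12)
})

test_that("image segmentation finds each implant and nothing else", {
  fx <- marFixture()
  ls <- fx$sim(fx$ph, 1e6)
  lsFree <- fx$sim(fx$phFree, 1e6)
  imgF <- fbp(ls, 256L)
  # metal-free image stays below 3000 HU everywhere
  expect_false(any(segmentImageMetal(fbp(lsFree, 256L), 3000, fx$muEff)))
  # +Inf threshold gives an empty mask
  expect_false(any(segmentImageMetal(imgF, Inf, fx$muEff)))
  mask <- segmentImageMetal(imgF, fx$thr$mar2, fx$muEff)
  expect_true(any(mask))
  skip_if_not_installed("EBImage")
  ncomp <- max(EBImage::bwlabel(mask))
  # 12 fillings + 2 cochlear + 2 deep-brain implants
  expect_equal(ncomp, 16)
})

test_that("MAR 2 covers the true metal trace and improves with dose", {
  fx <- marFixture()
  ls <- fx$sim(fx$ph, 1e6)
  imgF <- fbp(ls, 256L)
  maskImg <- segmentImageMetal(imgF, fx$thr$mar2, fx$muEff)
  trace <- maskToTrace(maskImg, fx$g, 26 / 256)
  analytic <- analyticIronTrace(fx$ph, fx$g) > 26 / 512
  # segmentation completeness: nearly all true metal bins are replaced
  expect_gte(mean(trace[analytic]), 0.99)
  # metal-free phantom: MAR 2 output equals plain FBP exactly
  lsFree <- fx$sim(fx$phFree, 1e6)
  imgFree <- fbp(lsFree, 256L)
  m2free <- mar2(lsFree, fx$thr$mar2, 256L, muWaterEff = fx$muEff,
                 fbpImage = imgFree)
  expect_identical(pixels(m2free), pixels(imgFree))
  expect_equal(reconMethod(m2free), "MAR2")
  # streak energy decreases monotonically as dose rises
  streaks <- vapply(c(1e5, 1e6, 1e7), function(I0) {
    lsI <- fx$sim(fx$ph, I0)
    refI <- pixels(fbp(fx$sim(fx$phFree, I0), 256L))
    m2 <- mar2(lsI, fx$thr$mar2, 256L, muWaterEff = fx$muEff)
    ironPx <- rasterizePhantom(fx$ph, 256L, 26)$channels$iron > 0
    d <- (pixels(m2) - refI)[!ironPx]
    sqrt(mean(d^2))
  }, numeric(1))
  expect_true(all(diff(streaks) < 0))
})
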