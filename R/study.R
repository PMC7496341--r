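#' Study condition
#'
#' Bundle of the imaging and task parameters a detectability measurement is
#' made at.
#'
#' @param amplitude signal amplitude relative to the inset background, in
#'   [1.00, 1.06].
#' @param dose unattenuated photons per bin per view (I0, a.u.).
#' @param methods reconstruction methods to run, subset of
#'   `c("FBP", "MAR1", "MAR2")`.
#' @param nImagesPerClass images per class (1000 at full scale).
#' @param masterSeed integer master seed; all per-image seeds derive from
#'   it.
#' @return list of class `"studyCondition"`.
#' @export
studyCondition <- function(amplitude = 1.03, dose = 1e6,
                           methods = c("FBP", "MAR1", "MAR2"),
                           nImagesPerClass = 1000L, masterSeed = 1L) {
  if (amplitude < 1.00 || amplitude > 1.06)
    stop("amplitude must lie in [1.00, 1.06]")
  methods <- match.arg(methods, c("FBP", "MAR1", "MAR2"),
                       several.ok = TRUE)
  structure(list(amplitude = amplitude, dose = dose, methods = methods,
                 nImagesPerClass = as.integer(nImagesPerClass),
                 masterSeed = as.integer(masterSeed)),
            class = "studyCondition")
}

#' Study presets
#'
#' `"full"` is the full-scale study (512 x 512 images over a 26 cm field,
#' 720 views x 729 bins, 121 x 121 ROI, 1000 images per class, NT from 25
#' to 1000, 50 repetitions, dose 1e6). `"scaled"` is the desk-scale preset
#' used by the bundled analyses: 256 x 256 images, 360 views, a 61 x 61
#' ROI (the same 6.2 cm patch as the full-scale 121 x 121 ROI, at the
#' display pitch), 200 images per class, NT {25, 50, 100}. The scaled
#' preset keeps the full-resolution detector (729 bins) so the
#' ramp-filtered noise bandwidth per pixel — and with it the difficulty of
#' the detection task at a given dose — stays in the regime of the
#' full-scale study rather than being averaged away by the coarser display
#' grid. `roiGrid` sets the pixel pitch the observer's ROI is
#' backprojected at (the stored image size by default in both presets).
#'
#' @param scale `"scaled"` or `"full"`.
#' @return list of geometry and study parameters.
#' @export
studyPreset <- function(scale = c("scaled", "full")) {
  scale <- match.arg(scale)
  if (scale == "full")
    list(geometry = projectionGeometry(720L, 729L, 26),
         gridSize = 512L, imageSize = 512L, roiSide = 121L,
         roiGrid = 512L, nImagesPerClass = 1000L,
         NT = c(25, 50, 100, 200, 500, 1000),
         repetitions = 50L, dose = 1e6, spectrumBin = 1,
         s0Frac = 1e-6, readoutSigma = 5, stepFrac = 0.5)
  else
    list(geometry = projectionGeometry(360L, 729L, 26),
         gridSize = 256L, imageSize = 256L, roiSide = 61L,
         roiGrid = 256L, nImagesPerClass = 200L, NT = c(25, 50, 100),
         repetitions = 50L, dose = 1e6, spectrumBin = 5,
         s0Frac = 1e-6, readoutSigma = 5, stepFrac = 1)
}

# Deterministic per-(dose, amplitude, class) seed, independent of sweep
# order so ensembles shared between sweeps are bit-identical.
.conditionSeed <- function(masterSeed, dose, amplitude, class) {
  m <- 2147483647
  h <- (as.numeric(masterSeed) * 2654435761) %% m
  h <- (h * 31 + round(log10(dose) * 1e4)) %% m
  h <- (h * 31 + round(amplitude * 1e4)) %% m
  h <- (h * 31 + class) %% m
  as.integer(h %% (m - 2) + 1)
}

# One acquisition: phantom at a random inset angle -> noisy log sinogram.
.simulateAcquisition <- function(seed, signalPresent, amplitude, lumpField,
                                 geom, gridSize, spectrum, tables, I0, s0,
                                 readoutSigma, stepFrac) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  angle <- runif(1, 0, 2 * pi)
  ph <- buildPhantom(insetAngle = angle, signalPresent = signalPresent,
                     signalAmplitude = amplitude, lumpField = lumpField)
  mats <- materialLineIntegrals(ph, geom, gridSize, stepFrac)
  cnt <- detectCounts(mats, spectrum, tables, I0 = I0, s0 = s0,
                      readoutSigma = readoutSigma, seed = seed)
  countsToLogSinogram(cnt)
}

.reconstructAll <- function(logsino, methods, imageSize, thresholds,
                            muWaterEff) {
  fbpImg <- fbp(logsino, imageSize)   # shared by MAR1 (no-op path) and MAR2
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      FBP = fbpImg,
      MAR1 = mar1(logsino, thresholds$mar1, imageSize, fbpImage = fbpImg),
      MAR2 = mar2(logsino, thresholds$mar2, imageSize,
                  muWaterEff = muWaterEff, fbpImage = fbpImg))
  }
  out
}

# Centered ROI reconstruction window matching extractROI()'s crop of a
# roiGrid-sized reconstruction (bit-identical backprojection arithmetic).
.roiWindow <- function(roiGrid, roiSide, fov) {
  px <- fov / roiGrid
  ctr <- floor((roiGrid + 1) / 2)
  h <- (roiSide - 1) / 2
  x0 <- ((ctr - h) - (roiGrid + 1) / 2) * px
  list(n = as.integer(roiSide), x0 = x0, y0 = x0)
}

# ROI vectors per method for one acquisition. ROIs are backprojected only
# over the observer's window, at the pixel pitch of a roiGrid-sized
# reconstruction (512 in both presets, so the observer sees the same
# 121 x 121 patch at the same pitch regardless of the stored image size);
# the full imageSize FBP image is still reconstructed for MAR 2's metal
# segmentation.
.reconstructROIs <- function(logsino, methods, imageSize, roiSide,
                             roiGrid, thresholds, muWaterEff) {
  win <- .roiWindow(roiGrid, roiSide, geometry(logsino)@fov)
  # the full image only feeds metal segmentation (and the central ROI
  # crop); everything of interest lies inside the r = 13 cm support
  fbpImg <- fbp(logsino, imageSize, supportRadius = 13.2)
  winVec <- function(sino)
    as.vector(t(pixels(fbp(sino, roiGrid, window = win))))
  fbpROI <- NULL
  getFbpROI <- function() {
    # when the ROI pitch matches the stored image, its window is a crop of
    # the already-reconstructed full FBP image
    if (is.null(fbpROI))
      fbpROI <<- if (roiGrid == imageSize) extractROI(fbpImg, roiSide)
                 else winVec(logsino)
    fbpROI
  }
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      FBP = getFbpROI(),
      MAR1 = {
        mask <- segmentSinogramMetal(logsino, thresholds$mar1)
        if (!any(mask)) getFbpROI()
        else winVec(inpaintTrace(logsino, mask))
      },
      MAR2 = {
        maskImg <- segmentImageMetal(fbpImg, thresholds$mar2, muWaterEff)
        if (!any(maskImg)) getFbpROI()
        else {
          trace <- maskToTrace(maskImg, geometry(logsino),
                               pixelSize(fbpImg))
          winVec(inpaintTrace(logsino, trace))
        }
      })
  }
  out
}

#' Generate ROI ensembles for a study condition
#'
#' For each image: a per-image seed (derived from the master seed and the
#' condition) fixes the inset angle (uniform on \eqn{[0, 2\pi)}) and the
#' detector noise; the acquisition is simulated, reconstructed with each
#' requested method, and the centered ROI extracted. One lumpy-background
#' realization (from `lumpSeed`) is shared by all acquisitions, mirroring a
#' single physical inset rotated between scans; set `resampleLumps = TRUE`
#' to draw a fresh field per image. Class 1 (absent) ensembles depend only
#' on dose, not amplitude. In paired mode the two classes share per-image
#' seeds (same angles and noise), a variance-reduction option; default
#' unpaired.
#'
#' @param condition a [studyCondition()].
#' @param preset a [studyPreset()] list (geometry, grids, ROI side, ...).
#' @param thresholds list with `mar1` (log-attenuation) and `mar2` (HU)
#'   segmentation thresholds, as from [calibrateThresholds()]; needed when
#'   the condition includes MAR methods.
#' @param spectrum,tables source spectrum and attenuation tables.
#' @param lumpSeed seed of the shared lumpy background.
#' @param paired logical; share per-image seeds between classes.
#' @param resampleLumps logical; fresh lump field per image.
#' @param cache optional environment reused across conditions so that
#'   ensembles shared between sweeps are computed once.
#' @param verbose print progress.
#' @return named list per method, each `list(absent =, present =)` with one
#'   ROI vector per row.
#' @export
generateEnsemble <- function(condition, preset = studyPreset("scaled"),
                             thresholds = NULL,
                             spectrum = rebinSpectrum(loadSpectrum(),
                                                      preset$spectrumBin),
                             tables = attenuationTables(),
                             lumpSeed = 1L, paired = FALSE,
                             resampleLumps = FALSE, cache = NULL,
                             verbose = FALSE) {
  geom <- preset$geometry
  n <- condition$nImagesPerClass
  I0 <- condition$dose
  s0 <- preset$s0Frac * I0
  muEff <- muWaterEffective(spectrum)
  needThr <- any(c("MAR1", "MAR2") %in% condition$methods)
  if (needThr && is.null(thresholds))
    stop("thresholds are required for MAR methods; run calibrateThresholds()")
  lf <- sampleLumpField(lumpSeed)
  q <- preset$roiSide^2

  oneClass <- function(class) {
    amp <- if (class == 2) condition$amplitude else 0
    key <- sprintf("d%g_a%g_c%d_n%d", I0, amp, class, n)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    baseSeed <- .conditionSeed(condition$masterSeed, I0,
                               if (paired) 0 else amp, class = if (paired) 1 else class)
    old <- .Random.seed_save()
    set.seed(baseSeed)
    seeds <- sample.int(2147483646L, n)
    .Random.seed_restore(old)
    rois <- lapply(condition$methods, function(m) matrix(0, n, q))
    names(rois) <- condition$methods
    for (i in seq_len(n)) {
      lfi <- if (resampleLumps) sampleLumpField(seeds[i] %% 1000000L + 1L)
             else lf
      ls <- .simulateAcquisition(seeds[i], class == 2, condition$amplitude,
                                 lfi, geom, preset$gridSize, spectrum,
                                 tables, I0, s0, preset$readoutSigma,
                                 preset$stepFrac)
      rv <- .reconstructROIs(ls, condition$methods, preset$imageSize,
                             preset$roiSide,
                             preset$roiGrid %||% preset$imageSize,
                             thresholds, muEff)
      for (m in condition$methods) rois[[m]][i, ] <- rv[[m]]
      if (verbose && i %% 25 == 0)
        message(sprintf("  class %d: %d / %d", class, i, n))
    }
    if (!is.null(cache)) cache[[key]] <- rois
    rois
  }

  absent <- oneClass(1)
  present <- oneClass(2)
  out <- lapply(condition$methods, function(m)
    list(absent = absent[[m]], present = present[[m]]))
  names(out) <- condition$methods
  out
}

#' Calibrate the MAR segmentation thresholds
#'
#' Thresholds are chosen once, at the middle of the parameter space
#' (amplitude 1.03, dose 1e6 by default), and then held fixed for every
#' other condition. MAR 1's log-attenuation threshold is the midpoint
#' between the 99.9th percentile of a metal-free acquisition's log sinogram
#' and the maximum log value over the analytic metal trace of a matched
#' acquisition with metal. MAR 2's HU threshold is the midpoint between the
#' 99.9th percentile of the metal-free reconstruction (in HU) and the
#' median HU over true metal pixels. Tying the upper anchor to the bulk of
#' the metal values (maximum / median rather than the trace fringe) puts
#' the threshold well inside the metal band, which is what a manual
#' mid-parameter selection achieves and what makes the segmentation fail
#' frankly once photon starvation caps the attainable log values at low
#' dose.
#'
#' @param preset a [studyPreset()] list.
#' @param amplitude,dose calibration condition.
#' @param spectrum,tables source spectrum and attenuation tables.
#' @param lumpSeed lumpy background seed.
#' @param seed acquisition seed for the calibration scans.
#' @return list with `mar1` (log-attenuation), `mar2` (HU), and the
#'   calibration anchors.
#' @export
calibrateThresholds <- function(preset = studyPreset("scaled"),
                                amplitude = 1.03, dose = 1e6,
                                spectrum = rebinSpectrum(loadSpectrum(),
                                                         preset$spectrumBin),
                                tables = attenuationTables(),
                                lumpSeed = 1L, seed = 20260930L) {
  geom <- preset$geometry
  s0 <- preset$s0Frac * dose
  lf <- sampleLumpField(lumpSeed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  angle <- runif(1, 0, 2 * pi)

  ph <- buildPhantom(insetAngle = angle, signalPresent = TRUE,
                     signalAmplitude = amplitude, lumpField = lf)
  phFree <- ph
  phFree@disks <- ph@disks[ph@disks$material != "iron", ]

  sim <- function(p) {
    mats <- materialLineIntegrals(p, geom, preset$gridSize, preset$stepFrac)
    countsToLogSinogram(detectCounts(mats, spectrum, tables, I0 = dose,
                                     s0 = s0,
                                     readoutSigma = preset$readoutSigma,
                                     seed = seed))
  }
  lsFree <- sim(phFree)
  lsMetal <- sim(ph)

  trace <- analyticIronTrace(ph, geom) > 0
  tFree <- quantile(sinogramValues(lsFree), 0.999, names = FALSE)
  tMetal <- max(sinogramValues(lsMetal)[trace])
  mar1Thr <- (tFree + tMetal) / 2

  muEff <- muWaterEffective(spectrum)
  huFree <- quantile(muToHu(fbp(lsFree, preset$imageSize), muEff), 0.999,
                     names = FALSE)
  ironMask <- rasterizePhantom(ph, preset$imageSize, geom@fov)$channels$iron > 0
  huMetal <- median(muToHu(fbp(lsMetal, preset$imageSize), muEff)[ironMask])
  mar2Thr <- (huFree + huMetal) / 2

  list(mar1 = mar1Thr, mar2 = mar2Thr,
       anchors = list(logFreeQ999 = tFree, logMetalMax = tMetal,
                      huFreeQ999 = huFree, huMetalMedian = huMetal),
       calibration = list(amplitude = amplitude, dose = dose, seed = seed,
                          lumpSeed = lumpSeed))
}

# internal: AUC from explicit train/test index sets
.aucSubset <- function(outputs, tr1, tr2, te1, te2) {
  train <- new("ChannelOutputs", v1 = outputs@v1[tr1, , drop = FALSE],
               v2 = outputs@v2[tr2, , drop = FALSE])
  tmpl <- trainCHO(train)
  t1 <- applyTemplate(tmpl, outputs@v1[te1, , drop = FALSE])
  t2 <- applyTemplate(tmpl, outputs@v2[te2, , drop = FALSE])
  aucBinormal(snrFromStatistics(t1, t2))
}

#' Resubstitution and hold-out AUC estimates
#'
#' Resubstitution draws NT images per class (without replacement), trains
#' the CHO on them and tests on the same images: positively biased.
#' Hold-out trains on NT per class and tests on the remaining N - NT:
#' negatively biased for finite NT. Both return the binormal AUC
#' \eqn{\Phi(SNR/\sqrt 2)}.
#'
#' @param outputs a [ChannelOutputs-class].
#' @param NT training images per class.
#' @param seed subset-draw seed.
#' @return AUC estimate.
#' @export
aucResubstitution <- function(outputs, NT, seed = 1L) {
  n1 <- nrow(outputs@v1); n2 <- nrow(outputs@v2)
  if (NT > n1 || NT > n2) stop("NT exceeds the available images per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  i1 <- sample.int(n1, NT); i2 <- sample.int(n2, NT)
  .aucSubset(outputs, i1, i2, i1, i2)
}

#' @rdname aucResubstitution
#' @export
aucHoldout <- function(outputs, NT, seed = 1L) {
  n1 <- nrow(outputs@v1); n2 <- nrow(outputs@v2)
  if (NT > n1 - 2 || NT > n2 - 2)
    stop(paste("hold-out requires NT <= images per class - 2 (the test-set",
               "variances need at least two images per class)"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  i1 <- sample.int(n1, NT); i2 <- sample.int(n2, NT)
  .aucSubset(outputs, i1, i2, setdiff(seq_len(n1), i1),
             setdiff(seq_len(n2), i2))
}

#' Antler-plot estimation
#'
#' For each training-set size NT and each repetition, draws a random subset
#' of the fixed ensemble and records both the resubstitution and hold-out
#' AUC. Subsets are drawn per repetition from the one ensemble, so the
#' spread across repetitions underestimates the true sampling error (the
#' repetitions are correlated); this is a property of the design, reported
#' as such.
#'
#' @param outputs a [ChannelOutputs-class].
#' @param NT vector of training sizes; values must stay below the ensemble
#'   size so both arms are defined.
#' @param repetitions number of random subsets per NT (default 50).
#' @param seed seed for all subset draws.
#' @return an [AntlerFit-class].
#' @export
antler <- function(outputs, NT = c(25, 50, 100), repetitions = 50L,
                   seed = 1L) {
  if (repetitions < 2) stop("repetitions must be at least 2")
  n1 <- nrow(outputs@v1); n2 <- nrow(outputs@v2)
  if (any(NT > min(n1, n2) - 2))
    stop("all NT must be smaller than the images per class minus one")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  res <- matrix(0, repetitions, length(NT))
  hol <- matrix(0, repetitions, length(NT))
  for (r in seq_len(repetitions)) {
    for (j in seq_along(NT)) {
      i1 <- sample.int(n1, NT[j]); i2 <- sample.int(n2, NT[j])
      res[r, j] <- .aucSubset(outputs, i1, i2, i1, i2)
      hol[r, j] <- .aucSubset(outputs, i1, i2,
                              setdiff(seq_len(n1), i1),
                              setdiff(seq_len(n2), i2))
    }
  }
  new("AntlerFit", NT = as.numeric(NT), resub = res, holdout = hol)
}

#' Per-NT summary of an antler fit
#'
#' @param fit an [AntlerFit-class].
#' @return data.frame with columns NT, arm, mean, sd.
#' @export
antlerSummary <- function(fit) {
  data.frame(
    NT = rep(fit@NT, 2),
    arm = rep(c("resubstitution", "holdout"), each = length(fit@NT)),
    mean = c(colMeans(fit@resub), colMeans(fit@holdout)),
    sd = c(apply(fit@resub, 2, sd), apply(fit@holdout, 2, sd)))
}

#' Extrapolate an antler plot to infinite training size
#'
#' Both arms of the antler plot are close to linear in 1/NT; each
#' repetition's arm is fit by ordinary least squares against 1/NT and
#' extrapolated to 1/NT = 0. The AUC-infinity estimate is the mean of the
#' two arms' mean intercepts; the bias error is half their difference; the
#' variance error is the standard deviation of the mean of the
#' per-repetition combined intercepts; the total is their root sum of
#' squares.
#'
#' @param fit an [AntlerFit-class] with at least 3 distinct NT values.
#' @return an [AUCExtrapolation-class].
#' @export
extrapolateAUC <- function(fit) {
  if (length(unique(fit@NT)) < 3)
    stop("extrapolation needs at least 3 distinct NT values")
  x <- 1 / fit@NT
  interceptOf <- function(y) unname(coef(lm(y ~ x))[1])
  intR <- apply(fit@resub, 1, interceptOf)
  intH <- apply(fit@holdout, 1, interceptOf)
  mR <- mean(intR); mH <- mean(intH)
  combined <- (intR + intH) / 2
  epsB <- abs(mR - mH) / 2
  epsV <- sd(combined) / sqrt(length(combined))
  new("AUCExtrapolation", aucInfResub = mR, aucInfHoldout = mH,
      aucInf = (mR + mH) / 2, epsB = epsB, epsV = epsV,
      eps = sqrt(epsB^2 + epsV^2))
}

#' Detectability curves over a parameter sweep
#'
#' Runs the full pipeline (ensemble generation, channelization, antler
#' estimation, extrapolation) for every condition in an amplitude or dose
#' sweep and every method, returning one row per (condition, method).
#' Signal-absent ensembles are shared across amplitudes at a given dose,
#' and conditions common to both sweeps are computed once when a shared
#' `cache` environment is supplied.
#'
#' @param sweep named list with exactly one of `amplitude` (vector) or
#'   `dose` (vector).
#' @param base a [studyCondition()] providing the non-swept parameters.
#' @param preset a [studyPreset()].
#' @param thresholds from [calibrateThresholds()].
#' @param NT,repetitions antler parameters (defaults from the preset).
#' @param bank channel bank; built for the preset's ROI if missing.
#' @param cache optional environment for cross-sweep ensemble reuse.
#' @param lumpSeed shared lumpy-background seed.
#' @param verbose print progress.
#' @return data.frame with columns: amplitude, dose, method, aucInf,
#'   aucInfResub, aucInfHoldout, epsB, epsV, eps, n.
#' @export
detectabilityCurve <- function(sweep, base, preset = studyPreset("scaled"),
                               thresholds = NULL, NT = preset$NT,
                               repetitions = preset$repetitions,
                               bank = NULL, cache = NULL, lumpSeed = 1L,
                               verbose = FALSE) {
  if (!(length(sweep) == 1 && names(sweep) %in% c("amplitude", "dose")))
    stop("sweep must be list(amplitude = ...) or list(dose = ...)")
  if (is.null(bank)) bank <- buildDDOGBank(preset$roiSide)
  spectrum <- rebinSpectrum(loadSpectrum(), preset$spectrumBin)
  tables <- attenuationTables()
  rows <- list()
  for (val in sweep[[1]]) {
    cond <- base
    if (names(sweep) == "amplitude") cond$amplitude <- val
    else cond$dose <- val
    if (verbose)
      message(sprintf("condition: amplitude %.2f, dose %g",
                      cond$amplitude, cond$dose))
    ens <- generateEnsemble(cond, preset, thresholds, spectrum, tables,
                            lumpSeed = lumpSeed, cache = cache,
                            verbose = verbose)
    for (m in cond$methods) {
      outputs <- channelizeClasses(ens[[m]]$absent, ens[[m]]$present, bank)
      fit <- antler(outputs, NT, repetitions,
                    seed = .conditionSeed(cond$masterSeed, cond$dose,
                                          cond$amplitude, 3L))
      ex <- extrapolateAUC(fit)
      rows[[length(rows) + 1]] <- data.frame(
        amplitude = cond$amplitude, dose = cond$dose, method = m,
        aucInf = ex@aucInf, aucInfResub = ex@aucInfResub,
        aucInfHoldout = ex@aucInfHoldout, epsB = ex@epsB, epsV = ex@epsV,
        eps = ex@eps, n = cond$nImagesPerClass)
    }
  }
  do.call(rbind, rows)
}

#' Run a configured study end to end
#'
#' Reads a configuration (YAML file path or list), calibrates the MAR
#' thresholds at the configured calibration condition, runs the requested
#' amplitude and/or dose sweeps, and writes per-condition extrapolation
#' tables (CSV), detectability-curve plots (PNG) and a JSON run manifest
#' capturing every seed, threshold and geometry parameter needed to
#' reproduce the outputs bit-identically.
#'
#' Required keys: `dose`, `amplitudes`, `nImagesPerClass`, `masterSeed`,
#' `outDir`. Optional: `doses` (dose sweep at `doseSweepAmplitude`, default
#' 1.03), `methods`, `preset` ("scaled"/"full"), `NT`, `repetitions`,
#' `lumpSeed`.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, list with the curve tables and the manifest.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("dose", "amplitudes", "nImagesPerClass", "masterSeed",
                "outDir")
  missingKeys <- setdiff(required, names(config))
  if (length(missingKeys))
    stop("missing required config keys: ",
         paste(missingKeys, collapse = ", "))
  known <- c(required, "doses", "doseSweepAmplitude", "methods", "preset",
             "NT", "repetitions", "lumpSeed", "imageSize", "gridSize", "roiGrid",
             "roiSide", "nViews", "nBins")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))

  preset <- studyPreset(config$preset %||% "scaled")
  for (k in c("imageSize", "gridSize", "roiSide", "roiGrid", "NT", "repetitions"))
    if (!is.null(config[[k]])) preset[[k]] <- config[[k]]
  if (!is.null(config$nViews) || !is.null(config$nBins))
    preset$geometry <- projectionGeometry(
      config$nViews %||% nViews(preset$geometry),
      config$nBins %||% nBins(preset$geometry))
  preset$nImagesPerClass <- config$nImagesPerClass
  methods <- config$methods %||% c("FBP", "MAR1", "MAR2")
  lumpSeed <- config$lumpSeed %||% 1L

  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  thr <- calibrateThresholds(preset, dose = config$dose,
                             lumpSeed = lumpSeed)
  base <- studyCondition(amplitude = config$amplitudes[1],
                         dose = config$dose, methods = methods,
                         nImagesPerClass = config$nImagesPerClass,
                         masterSeed = config$masterSeed)
  cache <- new.env(parent = emptyenv())
  ampCurve <- detectabilityCurve(list(amplitude = config$amplitudes), base,
                                 preset, thr, preset$NT,
                                 preset$repetitions, cache = cache,
                                 lumpSeed = lumpSeed)
  write.csv(ampCurve, file.path(config$outDir, "amplitude_curve.csv"),
            row.names = FALSE)
  doseCurve <- NULL
  if (!is.null(config$doses)) {
    base$amplitude <- config$doseSweepAmplitude %||% 1.03
    doseCurve <- detectabilityCurve(list(dose = config$doses), base,
                                    preset, thr, preset$NT,
                                    preset$repetitions, cache = cache,
                                    lumpSeed = lumpSeed)
    write.csv(doseCurve, file.path(config$outDir, "dose_curve.csv"),
              row.names = FALSE)
  }
  .plotCurves(ampCurve, doseCurve, config$outDir)

  manifest <- list(config = config, thresholds = thr[c("mar1", "mar2")],
                   geometry = list(nViews = nViews(preset$geometry),
                                   nBins = nBins(preset$geometry),
                                   binSpacing = binSpacing(preset$geometry),
                                   fov = fieldOfView(preset$geometry)),
                   preset = preset[c("gridSize", "imageSize", "roiSide",
                                     "NT", "repetitions", "spectrumBin",
                                     "s0", "readoutSigma", "stepFrac")],
                   lumpSeed = lumpSeed)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(amplitude = ampCurve, dose = doseCurve,
                 thresholds = thr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.plotCurves <- function(ampCurve, doseCurve, outDir) {
  plotOne <- function(tab, xvar, file, log = "") {
    grDevices::png(file.path(outDir, file), width = 700, height = 500)
    on.exit(grDevices::dev.off())
    methods <- unique(tab$method)
    cols <- c(FBP = "red3", MAR1 = "green4", MAR2 = "black")
    graphics::plot(range(tab[[xvar]]), range(tab$aucInf), type = "n",
                   xlab = xvar, ylab = "AUC (extrapolated)", log = log,
                   main = sprintf("Detectability vs %s", xvar))
    for (m in methods) {
      sub <- tab[tab$method == m, ]
      graphics::lines(sub[[xvar]], sub$aucInf, col = cols[[m]], type = "b",
                      pch = 16)
      graphics::arrows(sub[[xvar]], sub$aucInf - sub$eps, sub[[xvar]],
                       sub$aucInf + sub$eps, angle = 90, code = 3,
                       length = 0.03, col = cols[[m]])
    }
    graphics::legend("bottomright", legend = methods,
                     col = cols[methods], lty = 1, pch = 16)
  }
  plotOne(ampCurve, "amplitude", "amplitude_curve.png")
  if (!is.null(doseCurve)) plotOne(doseCurve, "dose", "dose_curve.png",
                                   log = "x")
}
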