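# Tiny simulation settings used for the pipeline-level study tests: a
# 128 x 128 grid with 180 views keeps each acquisition around 50 ms.
tinyPreset <- function(n = 10L) {
  pre <- studyPreset("scaled")
  pre$geometry <- projectionGeometry(180L, 365L, 26)
  pre$gridSize <- 128L
  pre$imageSize <- 128L
  pre$roiSide <- 31L
  pre$roiGrid <- 128L
  pre$nImagesPerClass <- n
  pre$NT <- c(12, 14, 16)   # must exceed the p = 10 channels
  pre$repetitions <- 5L
  pre$spectrumBin <- 10
  pre
}

test_that("study conditions validate their parameter ranges", {
  expect_error(studyCondition(amplitude = 1.2), "1.06")
  expect_error(studyCondition(methods = "SIRT"))
  cond <- studyCondition(1.05, 2e6, "FBP", 100L, 9L)
  expect_s3_class(cond, "studyCondition")
  expect_equal(cond$dose, 2e6)
})

test_that("ensembles are deterministic, class-consistent and counted", {
  pre <- tinyPreset(4L)
  cond <- studyCondition(1.05, 1e6, "FBP", 4L, masterSeed = 31L)
  e1 <- generateEnsemble(cond, pre)
  e2 <- generateEnsemble(cond, pre)
  expect_identical(e1, e2)
  expect_equal(dim(e1$FBP$absent), c(4, 31^2))
  expect_equal(dim(e1$FBP$present), c(4, 31^2))
  # a different master seed changes the realizations
  e3 <- generateEnsemble(studyCondition(1.05, 1e6, "FBP", 4L, 32L), pre)
  expect_false(identical(e1$FBP$absent, e3$FBP$absent))
  # absent ensembles do not depend on the signal amplitude
  e4 <- generateEnsemble(studyCondition(1.01, 1e6, "FBP", 4L, 31L), pre)
  expect_identical(e1$FBP$absent, e4$FBP$absent)
  expect_false(identical(e1$FBP$present, e4$FBP$present))
})

test_that("paired-seed classes differ only through the signal disk", {
  pre <- tinyPreset(2L)
  cond <- studyCondition(1.06, 1e6, "FBP", 2L, masterSeed = 7L)
  ens <- generateEnsemble(cond, pre, paired = TRUE)
  d <- abs(ens$FBP$present[1, ] - ens$FBP$absent[1, ])
  # the mean difference is concentrated at the signal disk; away from it
  # only re-drawn Poisson noise remains (identical seeds do not cancel
  # counting noise exactly because the class means differ)
  side <- 31L
  idx <- which(matrix(TRUE, side, side), arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 16)^2 + (idx[, 2] - 16)^2) * (26 / 128)
  rowMajorRad <- rad[order(idx[, 1], idx[, 2])]
  inner <- rowMajorRad < 0.7
  expect_gt(mean(abs(d[inner])), 3 * mean(abs(d[!inner])))
})

test_that("resubstitution and hold-out behave as biased AUC estimators", {
  sig <- designedSigma()
  dmu <- dmuForAUC(0.80, sig)
  out <- gaussianOutputs(400, dmu, sig, seed = 21)
  # determinism and the no-subsampling boundary case
  expect_equal(aucResubstitution(out, 400, seed = 1),
               aucResubstitution(out, 400, seed = 99))
  expect_equal(aucHoldout(out, 50, seed = 3), aucHoldout(out, 50, seed = 3))
  expect_error(aucResubstitution(out, 500), "exceeds")
  expect_error(aucHoldout(out, 400), "two images")
  # NT = N - 2 leaves two test images per class: legal but wild
  expect_true(is.finite(aucHoldout(out, 398, seed = 5)))
  # bias directions over repeated draws (analytic AUC = 0.80)
  resub <- vapply(1:200, function(s)
    aucResubstitution(out, 50, seed = s), numeric(1))
  hold <- vapply(1:200, function(s)
    aucHoldout(out, 50, seed = s), numeric(1))
  expect_gt(mean(resub), 0.80)
  expect_lt(mean(hold), 0.80)
  # the null case stays above 0.5 on average (finite-sample optimism)
  out0 <- gaussianOutputs(200, rep(0, 10), sig, seed = 22)
  resub0 <- vapply(1:100, function(s)
    aucResubstitution(out0, 40, seed = s), numeric(1))
  expect_gt(mean(resub0), 0.5)
})

test_that("antler estimation orders the arms and extrapolates correctly", {
  sig <- designedSigma()
  dmu <- dmuForAUC(0.85, sig)
  out <- gaussianOutputs(1000, dmu, sig, seed = 23)
  fit <- antler(out, NT = c(25, 50, 100, 200, 500), repetitions = 50L,
                seed = 2)
  expect_s4_class(fit, "AntlerFit")
  sm <- antlerSummary(fit)
  expect_equal(nrow(sm), 10)
  # bias ordering at every NT
  res <- colMeans(fit@resub); hol <- colMeans(fit@holdout)
  expect_true(all(res >= hol))
  # known-truth recovery within 3 eps
  ex <- extrapolateAUC(fit)
  expect_lt(abs(aucInf(ex) - 0.85), 3 * ex@eps + 0.005)
  expect_equal(ex@eps, sqrt(ex@epsB^2 + ex@epsV^2))
  expect_error(antler(out, NT = c(25, 50), repetitions = 1L), "repetitions")
  expect_error(antler(out, NT = 1500), "smaller")
  expect_error(extrapolateAUC(new("AntlerFit", NT = c(50, 50),
                                  resub = fit@resub[, 1:2],
                                  holdout = fit@holdout[, 1:2])),
               "distinct")
})

test_that("flat and two-intercept antler fits extrapolate by arithmetic", {
  NT <- c(25, 50, 100)
  flat <- new("AntlerFit", NT = NT,
              resub = matrix(0.9, 4, 3), holdout = matrix(0.9, 4, 3))
  exf <- extrapolateAUC(flat)
  expect_equal(aucInf(exf), 0.9)
  expect_equal(exf@epsB, 0)
  expect_equal(exf@epsV, 0)
  # arms converging to 0.92 and 0.90: AUCinf 0.91, epsB 0.01
  mk <- function(int, slope) t(vapply(1:6, function(r) int + slope / NT,
                                      numeric(3)))
  two <- new("AntlerFit", NT = NT, resub = mk(0.92, 0.5),
             holdout = mk(0.90, -0.5))
  ext <- extrapolateAUC(two)
  expect_equal(aucInf(ext), 0.91, tolerance = 1e-12)
  expect_equal(ext@epsB, 0.01, tolerance = 1e-12)
})

test_that("intercept convergence tightens as the ensemble grows", {
  sig <- designedSigma()
  dmu <- dmuForAUC(0.85, sig)
  gap <- vapply(c(250, 1000), function(n) {
    out <- gaussianOutputs(n, dmu, sig, seed = 24)
    fit <- antler(out, NT = pmin(c(25, 50, 100, 200), n / 2),
                  repetitions = 30L, seed = 3)
    ex <- extrapolateAUC(fit)
    abs(ex@aucInfResub - ex@aucInfHoldout)
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("a minimal study runs end to end and reproduces bit-identically", {
  outDir <- file.path(tempdir(), "marbench-smoke")
  unlink(outDir, recursive = TRUE)
  cfg <- list(dose = 1e6, amplitudes = c(1.03, 1.05),
              nImagesPerClass = 20L, masterSeed = 5L, outDir = outDir,
              preset = "scaled", imageSize = 128L, gridSize = 128L,
              roiSide = 31L, roiGrid = 128L, nViews = 180L, nBins = 365L,
              NT = c(12, 14, 16), repetitions = 5L,
              methods = c("FBP", "MAR2"))
  res <- runStudy(cfg)
  expect_true(file.exists(file.path(outDir, "amplitude_curve.csv")))
  expect_true(file.exists(file.path(outDir, "manifest.json")))
  expect_true(file.exists(file.path(outDir, "amplitude_curve.png")))
  tab <- read.csv(file.path(outDir, "amplitude_curve.csv"))
  expect_equal(nrow(tab), 4)   # 2 amplitudes x 2 methods
  expect_true(all(tab$aucInf > 0 & tab$aucInf <= 1.05))
  # re-running the same config reproduces the table exactly
  outDir2 <- file.path(tempdir(), "marbench-smoke2")
  cfg2 <- cfg; cfg2$outDir <- outDir2
  res2 <- runStudy(cfg2)
  expect_equal(res$amplitude, res2$amplitude, tolerance = 1e-14)
  # config validation names the offending keys
  expect_error(runStudy(cfg[setdiff(names(cfg), "dose")]), "dose")
  expect_error(runStudy(c(cfg, list(banana = 1))), "banana")
  unlink(c(outDir, outDir2), recursive = TRUE)
})
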