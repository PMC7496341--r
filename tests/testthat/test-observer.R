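test_that("ROI extraction crops, vectorizes row-major and validates", {
  img <- matrix(seq_len(128 * 128), 128, 128)
  expect_length(extractROI(img, 121L), 121^2)
  expect_length(extractROI(img, 1L), 1)
  # the single center pixel matches the documented convention
  expect_equal(extractROI(img, 1L), img[64, 64])
  # constant image -> constant vector
  expect_true(all(extractROI(matrix(7, 128, 128), 61L) == 7))
  # row-major: consecutive entries walk along a row (column index)
  v <- extractROI(img, 3L)
  expect_equal(v[2] - v[1], 128)   # next column in this matrix layout
  expect_error(extractROI(img, 60L), "odd")
  expect_error(extractROI(img, 129L), "larger")
})

test_that("the DDOG bank has p zero-DC, unit-norm, ordered channels", {
  bank <- buildDDOGBank(61L)
  U <- channelMatrix(bank)
  expect_equal(ncol(U), 10)
  expect_equal(nrow(U), 61^2)
  expect_equal(sqrt(colSums(U^2)), rep(1, 10), tolerance = 1e-12)
  # zero DC response: C_j(0) = 0 means the spatial channel sums to zero
  expect_lt(max(abs(colSums(U))), 1e-8)
  # frequency profile is zero at rho = 0 and peaks at increasing rho
  rho <- seq(0, 0.5, by = 1e-4)
  peaks <- vapply(1:10, function(j) {
    prof <- ddogProfile(bank, j, rho)
    expect_equal(prof[1], 0)
    rho[which.max(prof)]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # radial symmetry in the spatial domain: a channel equals its transpose
  u5 <- matrix(U[, 5], 61, 61, byrow = TRUE)
  expect_equal(u5, t(u5), tolerance = 1e-10)
  expect_equal(u5, u5[61:1, 61:1], tolerance = 1e-10)
})

test_that("channelization is the linear map U^T g", {
  bank <- buildDDOGBank(31L, p = 6)
  U <- channelMatrix(bank)
  expect_true(all(channelize(rep(0, 31^2), bank) == 0))
  # feeding channel columns back recovers near-identity (unit norms,
  # off-diagonals are the cross-channel overlaps)
  G <- t(U)
  V <- channelize(G, bank)
  expect_equal(diag(V), rep(1, 6), tolerance = 1e-10)
  # linearity
  set.seed(1)
  g1 <- rnorm(31^2); g2 <- rnorm(31^2)
  expect_equal(channelize(g1 + g2, bank),
               channelize(g1, bank) + channelize(g2, bank),
               tolerance = 1e-10)
  expect_error(channelize(rnorm(10), bank), "match")
})

test_that("trainCHO recovers the analytic Hotelling template", {
  sig <- designedSigma()
  dmu <- dmuForAUC(0.85, sig)
  # degenerate cases first: identical classes give a zero template
  out0 <- gaussianOutputs(500, rep(0, 10), sig, seed = 2)
  w0 <- trainCHO(out0)@w
  expect_lt(sqrt(sum(w0^2)), 0.2)
  # whitened data: template equals the mean difference
  outI <- gaussianOutputs(2e5, dmu, diag(10), seed = 3)
  tmplI <- trainCHO(outI)
  expect_lt(sqrt(sum((tmplI@w - dmu)^2)) / sqrt(sum(dmu^2)), 0.02)
  # designed covariance: template matches sigma^{-1} dmu within 2%
  out <- gaussianOutputs(1e5, dmu, sig, seed = 4)
  tmpl <- trainCHO(out)
  wTrue <- solve(sig, dmu)
  expect_lt(sqrt(sum((tmpl@w - wTrue)^2)) / sqrt(sum(wTrue^2)), 0.02)
  # too few training vectors is an error
  tiny <- new("ChannelOutputs", v1 = out@v1[1:5, ], v2 = out@v2[1:5, ])
  expect_error(trainCHO(tiny), "training")
})

test_that("applyTemplate produces w^T v with affine equivariance", {
  w <- c(1, -2, 0.5)
  tmpl <- new("CHOTemplate", w = w, deltaMu = w, sigma = diag(3))
  expect_equal(applyTemplate(tmpl, matrix(0, 4, 3)), rep(0, 4))
  v <- w / sum(w^2)
  expect_equal(applyTemplate(tmpl, v), 1)
  set.seed(5)
  V <- matrix(rnorm(30), 10, 3)
  shift <- c(3, 1, -2)
  expect_equal(applyTemplate(tmpl, sweep(V, 2, shift, "+")),
               applyTemplate(tmpl, V) + sum(w * shift),
               tolerance = 1e-12)
})

test_that("SNR and binormal AUC follow their closed forms", {
  expect_equal(snrFromStatistics(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  t1 <- rnorm(1e6); t2 <- rnorm(1e6, mean = 2)
  expect_equal(snrFromStatistics(t1, t2), 2, tolerance = 0.01)
  # unequal variances: means 0 and 2, variances 1 and 3 -> SNR = sqrt(2)
  t2b <- rnorm(1e6, 2, sqrt(3))
  expect_equal(snrFromStatistics(t1, t2b), sqrt(2), tolerance = 0.01)
  expect_error(snrFromStatistics(1, c(1, 2)), "at least 2")
  expect_error(snrFromStatistics(c(1, 1), c(1, 1)), "variance")
  expect_equal(aucBinormal(0), 0.5)
  expect_equal(aucBinormal(1e9), 1)
  expect_equal(aucBinormal(sqrt(2)), pnorm(1))
})

test_that("empirical AUC matches brute-force pair counting", {
  expect_equal(aucEmpirical(c(0, 1), c(2, 3)), 1)
  expect_equal(aucEmpirical(0, 0), 0.5)
  expect_equal(aucEmpirical(c(2, 3), c(0, 1)), 0)
  # brute force over all pairs on a random small case
  set.seed(7)
  t1 <- sample(1:6, 15, replace = TRUE)
  t2 <- sample(2:8, 11, replace = TRUE)
  brute <- mean(outer(t1, t2, function(a, b)
    (b > a) + 0.5 * (b == a)))
  expect_equal(aucEmpirical(t1, t2), brute)
})

test_that("binormal and Mann-Whitney AUC agree for Gaussian statistics", {
  set.seed(8)
  for (snr in c(0.5, 1.5, 3)) {
    t1 <- rnorm(1e5); t2 <- rnorm(1e5, snr)
    expect_lt(abs(aucBinormal(snrFromStatistics(t1, t2)) -
                    aucEmpirical(t1, t2)), 0.005)
  }
})

test_that("the CHO is invariant to invertible channel transforms", {
  sig <- designedSigma()
  dmu <- dmuForAUC(0.8, sig)
  out <- gaussianOutputs(4000, dmu, sig, seed = 9)
  snr0 <- {
    tmpl <- trainCHO(out)
    snrFromStatistics(applyTemplate(tmpl, out@v1),
                      applyTemplate(tmpl, out@v2))
  }
  set.seed(10)
  A <- matrix(rnorm(100), 10, 10) + 5 * diag(10)  # invertible
  outT <- new("ChannelOutputs", v1 = out@v1 %*% A, v2 = out@v2 %*% A)
  tmplT <- trainCHO(outT)
  snrT <- snrFromStatistics(applyTemplate(tmplT, outT@v1),
                            applyTemplate(tmplT, outT@v2))
  expect_equal(snrT, snr0, tolerance = 1e-8)
})

test_that("adding a constant image to every ROI leaves the AUC unchanged", {
  # deterministic streaks add the same offset to both classes and cancel
  bank <- buildDDOGBank(31L, p = 8)
  q <- 31^2
  set.seed(11)
  base <- matrix(rnorm(400 * q, sd = 0.01), 400, q)
  signal <- as.vector(t(outer(-15:15, -15:15,
                              function(i, j) 0.005 * (i^2 + j^2 < 16))))
  rois1 <- base[1:200, ]
  rois2 <- sweep(base[201:400, ], 2, signal, "+")
  streak <- rnorm(q, sd = 0.5)
  auc <- function(r1, r2) {
    o <- channelizeClasses(r1, r2, bank)
    tmpl <- trainCHO(o)
    aucBinormal(snrFromStatistics(applyTemplate(tmpl, o@v1),
                                  applyTemplate(tmpl, o@v2)))
  }
  a0 <- auc(rois1, rois2)
  a1 <- auc(sweep(rois1, 2, streak, "+"), sweep(rois2, 2, streak, "+"))
  expect_equal(a1, a0, tolerance = 1e-6)
})
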