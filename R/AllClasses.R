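#' @import methods
#' @importFrom stats approx cov fft mvfft pnorm quantile rnorm rpois runif sd
#'   var coef lm median
#' @importFrom utils read.table write.csv
#' @useDynLib MARbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Energy-dependent linear attenuation table
#'
#' Tabulated linear attenuation coefficients \eqn{\mu(E)} (1/cm) for one
#' phantom material on an ascending keV grid. Values between grid points are
#' obtained by log-log interpolation (see [interpolateMu()]), the standard
#' scheme for smooth photon cross sections away from absorption edges.
#'
#' @slot material material label, e.g. `"water"`.
#' @slot energies ascending photon energies, keV.
#' @slot mu linear attenuation coefficients, 1/cm, all positive.
#' @export
setClass("AttenuationTable",
  representation(material = "character", energies = "numeric", mu = "numeric"))

setValidity("AttenuationTable", function(object) {
  msg <- character()
  if (length(object@energies) != length(object@mu))
    msg <- c(msg, "energies and mu must have equal length")
  if (any(diff(object@energies) <= 0))
    msg <- c(msg, "energies must be strictly increasing")
  if (any(object@mu <= 0))
    msg <- c(msg, "all mu values must be positive")
  if (length(object@energies) &&
      (min(object@energies) > 10 || max(object@energies) < 120))
    msg <- c(msg, "energy grid must span at least [10, 120] keV")
  if (length(msg)) msg else TRUE
})

#' X-ray tube spectrum
#'
#' Relative photon fluence per energy bin for a polychromatic source,
#' normalized to sum to one. Bins above the tube voltage carry zero weight.
#'
#' @slot energies keV grid.
#' @slot weights nonnegative relative fluence, summing to 1.
#' @slot kvp tube voltage, kV.
#' @export
setClass("Spectrum",
  representation(energies = "numeric", weights = "numeric", kvp = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@energies) != length(object@weights))
    msg <- c(msg, "energies and weights must have equal length")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 within 1e-12")
  if (any(object@weights[object@energies > object@kvp] > 0))
    msg <- c(msg, "weights above the tube voltage must be zero")
  if (length(msg)) msg else TRUE
})

#' Parallel-beam projection geometry
#'
#' @slot nViews number of view angles, uniformly spaced over \eqn{[0, \pi)};
#'   at least 180.
#' @slot nBins number of detector bins; odd, so the central bin sits on the
#'   rotation axis.
#' @slot binSpacing detector bin spacing, cm.
#' @slot fov reconstruction field of view (image side length), cm.
#' @export
setClass("ProjectionGeometry",
  representation(nViews = "integer", nBins = "integer",
                 binSpacing = "numeric", fov = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  msg <- character()
  if (object@nViews < 180L) msg <- c(msg, "nViews must be >= 180")
  if (object@nBins %% 2L == 0L) msg <- c(msg, "nBins must be odd")
  if (object@nBins * object@binSpacing < 24)
    msg <- c(msg, "detector extent must cover the 24 cm phantom diameter")
  if (length(msg)) msg else TRUE
})

#' Random lumpy-background field
#'
#' A realization of the inset texture: `n` Gaussian lumps
#' \eqn{\mu_i e^{-\pi |r - r_i|^2 / w_i^2}} with random centers inside the
#' inset, random widths and signed random amplitudes (expressed as multiples
#' of the water attenuation coefficient).
#'
#' @slot centers n x 2 matrix of lump centers, cm (inset frame, angle 0).
#' @slot widths lump widths \eqn{w_i}, cm, all >= 0.2.
#' @slot amplitudes lump amplitudes in multiples of \eqn{\mu_{water}}.
#' @slot seed integer seed the field was drawn from.
#' @export
setClass("LumpField",
  representation(centers = "matrix", widths = "numeric",
                 amplitudes = "numeric", seed = "integer"))

setValidity("LumpField", function(object) {
  msg <- character()
  n <- nrow(object@centers)
  if (ncol(object@centers) != 2) msg <- c(msg, "centers must be n x 2")
  if (length(object@widths) != n || length(object@amplitudes) != n)
    msg <- c(msg, "widths and amplitudes must match number of centers")
  if (any(object@widths <= 0)) msg <- c(msg, "widths must be positive")
  if (any(sqrt(rowSums(object@centers^2)) >= 4.9))
    msg <- c(msg, "lump centers must satisfy |r_i| < 4.9 cm")
  if (length(msg)) msg else TRUE
})

#' A realized head phantom
#'
#' Disk primitives (skull, brain, rotatable inset, teeth, dental fillings,
#' cochlear and deep-brain implants, optional central signal) plus one lumpy
#' background realization. The inset contents (lumps, deep-brain implants,
#' signal neighbourhood) rotate rigidly by `insetAngle`; all other metal is
#' fixed.
#'
#' @slot disks data.frame of disk primitives: name, x, y (cm), r (cm),
#'   material (`water`/`bone`/`iron`), scale (multiplier on the material's
#'   \eqn{\mu(E)}), rotates (logical, rotates with the inset).
#' @slot lumpField a [LumpField-class].
#' @slot insetAngle inset rotation, radians, counter-clockwise.
#' @slot signalPresent logical.
#' @slot signalAmplitude signal amplitude relative to the inset base
#'   material, in [1.00, 1.06].
#' @export
setClass("PhantomInstance",
  representation(disks = "data.frame", lumpField = "LumpField",
                 insetAngle = "numeric", signalPresent = "logical",
                 signalAmplitude = "numeric"))

setValidity("PhantomInstance", function(object) {
  msg <- character()
  need <- c("name", "x", "y", "r", "material", "scale", "rotates")
  if (!all(need %in% names(object@disks)))
    msg <- c(msg, paste("disks must have columns:", paste(need, collapse = ", ")))
  if (any(object@disks$r <= 0)) msg <- c(msg, "disk radii must be positive")
  if (object@signalPresent &&
      (object@signalAmplitude < 1.00 || object@signalAmplitude > 1.06))
    msg <- c(msg, "signalAmplitude must lie in [1.00, 1.06]")
  if (length(msg)) msg else TRUE
})

#' Per-material path-length sinograms
#'
#' One nViews x nBins sinogram of path lengths (cm, already weighted by any
#' material scale factor) per material channel, on a fixed parallel-beam
#' geometry.
#'
#' @slot sinograms named list of matrices (water/bone/iron), path length cm.
#' @slot geometry the [ProjectionGeometry-class] used.
#' @export
setClass("MaterialSinograms",
  representation(sinograms = "list", geometry = "ProjectionGeometry"))

setValidity("MaterialSinograms", function(object) {
  g <- object@geometry
  ok <- vapply(object@sinograms, function(m)
    is.matrix(m) && all(dim(m) == c(g@nViews, g@nBins)) &&
      all(is.finite(m)) && all(m >= 0), logical(1))
  if (!all(ok)) "each sinogram must be a finite nonnegative nViews x nBins matrix"
  else TRUE
})

#' Detected photon counts
#'
#' @slot counts nViews x nBins detected photons (non-integer once Gaussian
#'   readout noise is added).
#' @slot I0 unattenuated photons per bin per view (the "dose", a.u.).
#' @slot s0 constant scatter mean, photons per bin per view.
#' @slot readoutSigma readout noise standard deviation, photons.
#' @slot seed integer seed (NA for noiseless data).
#' @slot geometry the [ProjectionGeometry-class] used.
#' @export
setClass("CountsSinogram",
  representation(counts = "matrix", I0 = "numeric", s0 = "numeric",
                 readoutSigma = "numeric", seed = "integer",
                 geometry = "ProjectionGeometry"))

setValidity("CountsSinogram", function(object) {
  g <- object@geometry
  msg <- character()
  if (!all(dim(object@counts) == c(g@nViews, g@nBins)))
    msg <- c(msg, "counts shape must match geometry")
  if (object@I0 <= 0) msg <- c(msg, "I0 must be positive")
  if (object@s0 < 0) msg <- c(msg, "s0 must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Log-attenuation sinogram
#'
#' \eqn{-\ln(\max(c, 1) / (I_0 + s_0))} per bin; the clip at one count keeps
#' photon-starved bins finite.
#'
#' @slot values nViews x nBins log-attenuation values, finite.
#' @slot I0,s0 flat-field parameters the log was taken against.
#' @slot geometry the [ProjectionGeometry-class] used.
#' @export
setClass("LogSinogram",
  representation(values = "matrix", I0 = "numeric", s0 = "numeric",
                 geometry = "ProjectionGeometry"))

setValidity("LogSinogram", function(object) {
  g <- object@geometry
  if (!all(dim(object@values) == c(g@nViews, g@nBins)))
    "values shape must match geometry"
  else if (!all(is.finite(object@values))) "values must be finite"
  else TRUE
})

#' Reconstructed attenuation image
#'
#' @slot pixels square matrix of linear attenuation, 1/cm.
#' @slot pixelSize pixel side, cm.
#' @slot method reconstruction pipeline: `"FBP"`, `"MAR1"` or `"MAR2"`.
#' @slot params list of provenance parameters (thresholds, seeds, ...).
#' @export
setClass("ReconImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 method = "character", params = "list"))

setValidity("ReconImage", function(object) {
  if (nrow(object@pixels) != ncol(object@pixels)) "image must be square"
  else if (!all(is.finite(object@pixels))) "pixel values must be finite"
  else TRUE
})

#' Dense difference-of-Gaussians channel bank
#'
#' @slot U q x p matrix of unit-normalized spatial-domain channel images
#'   (columns), q = roiSide^2, row-major vectorization.
#' @slot roiSide ROI side length, pixels (odd).
#' @slot params list(p, sigma0, alpha, Q) of the radial-frequency profile
#'   parameters.
#' @export
setClass("ChannelBank",
  representation(U = "matrix", roiSide = "integer", params = "list"))

setValidity("ChannelBank", function(object) {
  msg <- character()
  if (nrow(object@U) != object@roiSide^2)
    msg <- c(msg, "U must have roiSide^2 rows")
  if (ncol(object@U) >= nrow(object@U))
    msg <- c(msg, "number of channels must be much smaller than q")
  nrm <- sqrt(colSums(object@U^2))
  if (any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "channel columns must be unit-normalized")
  if (length(msg)) msg else TRUE
})

#' Channel outputs for the two hypothesis classes
#'
#' Rows are per-image p-vectors \eqn{v = U^T g}; class 1 is signal absent,
#' class 2 signal present.
#'
#' @slot v1 n1 x p matrix, signal absent.
#' @slot v2 n2 x p matrix, signal present.
#' @export
setClass("ChannelOutputs", representation(v1 = "matrix", v2 = "matrix"))

setValidity("ChannelOutputs", function(object) {
  if (ncol(object@v1) != ncol(object@v2))
    "both classes must have the same channel dimension"
  else TRUE
})

#' Trained channelized Hotelling template
#'
#' @slot w p-vector template, solving \eqn{\Sigma w = \Delta\mu}.
#' @slot deltaMu class-mean difference (present minus absent).
#' @slot sigma pooled p x p channel covariance, symmetric positive definite.
#' @export
setClass("CHOTemplate",
  representation(w = "numeric", deltaMu = "numeric", sigma = "matrix"))

#' Antler-plot data
#'
#' Resubstitution and hold-out AUC over a grid of training-set sizes NT,
#' repeated over random subsets of a fixed image ensemble.
#'
#' @slot NT training-set sizes.
#' @slot resub repetitions x length(NT) matrix of resubstitution AUC.
#' @slot holdout repetitions x length(NT) matrix of hold-out AUC.
#' @export
setClass("AntlerFit",
  representation(NT = "numeric", resub = "matrix", holdout = "matrix"))

setValidity("AntlerFit", function(object) {
  msg <- character()
  if (ncol(object@resub) != length(object@NT) ||
      ncol(object@holdout) != length(object@NT))
    msg <- c(msg, "AUC matrices must have one column per NT")
  if (nrow(object@resub) != nrow(object@holdout))
    msg <- c(msg, "both arms must have the same number of repetitions")
  if (length(msg)) msg else TRUE
})

#' Extrapolated AUC with bias and variance uncertainty
#'
#' Ordinary least squares of mean AUC against 1/NT per arm; the intercepts
#' estimate the infinitely-trained AUC. `eps = sqrt(epsB^2 + epsV^2)`.
#'
#' @slot aucInfResub,aucInfHoldout per-arm intercepts (means over
#'   repetitions of the per-repetition intercepts).
#' @slot aucInf their mean, the AUC-infinity estimate.
#' @slot epsB bias component: half the intercept difference.
#' @slot epsV variance component: standard deviation of the mean of the
#'   per-repetition intercepts.
#' @slot eps root-sum-square total uncertainty.
#' @export
setClass("AUCExtrapolation",
  representation(aucInfResub = "numeric", aucInfHoldout = "numeric",
                 aucInf = "numeric", epsB = "numeric", epsV = "numeric",
                 eps = "numeric"))

setValidity("AUCExtrapolation", function(object) {
  if (abs(object@eps - sqrt(object@epsB^2 + object@epsV^2)) > 1e-9)
    "eps must equal sqrt(epsB^2 + epsV^2)"
  else TRUE
})
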