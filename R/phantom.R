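#' Draw a random lumpy-background field
#'
#' The inset texture is a sum of `n` Gaussian lumps
#' \eqn{\sum_i \mu_i e^{-\pi |r - r_i|^2 / w_i^2}}. Centers are uniform in
#' the disk \eqn{|r_i| < 4.9} cm (keeping lumps inside the 5.9 cm inset),
#' widths are \eqn{w_i = 1.3 + 2R} cm with \eqn{R \sim N(0,1)}, clamped
#' below at 0.2 cm, and amplitudes are \eqn{\mu_i = 1.5\,\mu_{water} R'}
#' with \eqn{R' \sim U(-1,1)} (amplitudes are stored as the dimensionless
#' multiple of \eqn{\mu_{water}}). The draw order (centers, widths,
#' amplitudes) is fixed, so a seed fully determines the field.
#'
#' @param seed integer seed.
#' @param n number of lumps (default 20).
#' @return a [LumpField-class].
#' @examples
#' sampleLumpField(7)
#' @export
sampleLumpField <- function(seed, n = 20L) {
  seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rad <- 4.9 * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  centers <- cbind(x = rad * cos(phi), y = rad * sin(phi))
  widths <- pmax(1.3 + 2 * rnorm(n), 0.2)
  amplitudes <- 1.5 * runif(n, -1, 1)
  new("LumpField", centers = centers, widths = widths,
      amplitudes = amplitudes, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Head-phantom disk primitives
#'
#' The fixed disk layout: a 12 cm bone outer disk (skull), 10 cm water inner
#' disk, 5.9 cm rotatable inset at 1.05 x water, twelve teeth at
#' \eqn{(7\cos(n\pi/11), 9\sin(n\pi/11))} with 0.2 cm iron fillings at the
#' same centers, iron cochlear implants at (+-11, 0), and iron deep-brain
#' implants at (+-1, -5.1) that rotate with the inset.
#'
#' @param teethMaterial material of the tooth disks; defaults to `"bone"`
#'   (teeth carry separate 0.2 cm iron fillings), `"iron"` supported.
#' @return data.frame of disk primitives in painting order.
#' @export
phantomDisks <- function(teethMaterial = c("bone", "iron")) {
  teethMaterial <- match.arg(teethMaterial)
  n <- 0:11
  tx <- 7 * cos(n * pi / 11)
  ty <- 9 * sin(n * pi / 11)
  rbind(
    data.frame(name = "outer", x = 0, y = 0, r = 12, material = "bone",
               scale = 1, rotates = FALSE),
    data.frame(name = "inner", x = 0, y = 0, r = 10, material = "water",
               scale = 1, rotates = FALSE),
    data.frame(name = "inset", x = 0, y = 0, r = 5.9, material = "water",
               scale = 1.05, rotates = FALSE),
    data.frame(name = sprintf("tooth%02d", n), x = tx, y = ty, r = 0.7,
               material = teethMaterial, scale = 1, rotates = FALSE),
    data.frame(name = sprintf("filling%02d", n), x = tx, y = ty, r = 0.2,
               material = "iron", scale = 1, rotates = FALSE),
    data.frame(name = c("cochlearL", "cochlearR"), x = c(-11, 11), y = 0,
               r = 0.6, material = "iron", scale = 1, rotates = FALSE),
    data.frame(name = c("dbsL", "dbsR"), x = c(-1, 1), y = -5.1, r = 0.3,
               material = "iron", scale = 1, rotates = TRUE))
}

#' Build a phantom instance
#'
#' Assembles the head phantom at a given inset rotation with one lumpy
#' background realization and an optional central signal disk. The signal
#' (0.5 cm radius, centered) is a homogeneous rod that *replaces* the local
#' background: within the signal disk the lump contribution is removed and
#' the attenuation is `signalAmplitude` times the inset base material
#' (1.05 x water).
#'
#' @param insetAngle inset rotation, radians (counter-clockwise).
#' @param signalPresent logical.
#' @param signalAmplitude in [1.00, 1.06]; required when the signal is
#'   present.
#' @param lumpField a [LumpField-class], or `NULL` to draw one from
#'   `lumpSeed`.
#' @param lumpSeed seed used when `lumpField` is `NULL`.
#' @param teethMaterial see [phantomDisks()].
#' @return a [PhantomInstance-class].
#' @examples
#' buildPhantom(insetAngle = 0.3, signalPresent = TRUE,
#'              signalAmplitude = 1.03, lumpSeed = 1)
#' @export
buildPhantom <- function(insetAngle = 0, signalPresent = FALSE,
                         signalAmplitude = 1.0, lumpField = NULL,
                         lumpSeed = 1L,
                         teethMaterial = c("bone", "iron")) {
  if (signalPresent && (signalAmplitude < 1.00 || signalAmplitude > 1.06))
    stop("signalAmplitude must lie in [1.00, 1.06]")
  if (is.null(lumpField)) lumpField <- sampleLumpField(lumpSeed)
  new("PhantomInstance", disks = phantomDisks(teethMaterial),
      lumpField = lumpField, insetAngle = insetAngle,
      signalPresent = isTRUE(signalPresent),
      signalAmplitude = signalAmplitude)
}

.rot <- function(xy, angle) {
  if (angle == 0) return(xy)
  c(cos(angle) * xy[1] - sin(angle) * xy[2],
    sin(angle) * xy[1] + cos(angle) * xy[2])
}

.pixelCoords <- function(gridSize, fov) {
  (seq_len(gridSize) - (gridSize + 1) / 2) * (fov / gridSize)
}

#' Rasterize a lump field
#'
#' Evaluates the raw (unmasked) Gaussian lump sum on a pixel grid, in
#' multiples of \eqn{\mu_{water}}. Each lump is separable in x and y, so the
#' map is built from outer products of 1-D Gaussian profiles.
#'
#' @param lumpField a [LumpField-class].
#' @param gridSize image side, pixels.
#' @param fov field of view, cm.
#' @param angle rigid rotation applied to the lump centers, radians.
#' @return gridSize x gridSize matrix (rows index y, columns x).
#' @export
rasterizeLumpField <- function(lumpField, gridSize, fov = 26, angle = 0) {
  xs <- .pixelCoords(gridSize, fov)
  out <- matrix(0, gridSize, gridSize)
  for (i in seq_along(lumpField@widths)) {
    c2 <- .rot(lumpField@centers[i, ], angle)
    w <- lumpField@widths[i]
    gx <- exp(-pi * (xs - c2[1])^2 / w^2)
    gy <- exp(-pi * (xs - c2[2])^2 / w^2)
    out <- out + lumpField@amplitudes[i] * outer(gy, gx)
  }
  out
}

#' Rasterize a phantom into per-material weight maps
#'
#' Produces one map per material channel (`water`, `bone`, `iron`) such that
#' the attenuation image at energy E is
#' \eqn{W(x)\mu_{water}(E) + B(x)\mu_{bone}(E) + I(x)\mu_{iron}(E)}. Scaled
#' materials (the 1.05 x water inset, lump amplitudes, signal) are folded
#' into the water weight. Disks are painted in order with pixel-center
#' sampling and a strict Euclidean inside test; lumps are added inside the
#' inset wherever no implant sits; when the signal is present, the lump
#' contribution inside the signal disk is zeroed and the base weight
#' overridden. The composite water weight is clamped at zero so the phantom
#' stays physical under negative lump amplitudes.
#'
#' @param phantom a [PhantomInstance-class].
#' @param gridSize image side, pixels (>= 128).
#' @param fov field of view, cm (>= 24, the phantom diameter).
#' @return list with `channels` (named list of matrices), `pixelSize` (cm)
#'   and `fov`.
#' @export
rasterizePhantom <- function(phantom, gridSize = 256L, fov = 26) {
  stopifnot(is(phantom, "PhantomInstance"))
  if (gridSize < 128) stop("gridSize must be at least 128")
  if (fov < 24) stop("fov must be at least 24 cm to contain the outer disk")
  xs <- .pixelCoords(gridSize, fov)
  X <- matrix(xs, gridSize, gridSize, byrow = TRUE)   # columns index x
  Y <- matrix(xs, gridSize, gridSize)                 # rows index y
  ch <- list(water = matrix(0, gridSize, gridSize),
             bone = matrix(0, gridSize, gridSize),
             iron = matrix(0, gridSize, gridSize))
  paint <- function(center, r, material, scale) {
    m <- (X - center[1])^2 + (Y - center[2])^2 < r^2
    for (nm in names(ch)) ch[[nm]][m] <<- 0
    ch[[material]][m] <<- ch[[material]][m] + scale
  }
  d <- phantom@disks
  for (k in seq_len(nrow(d))) {
    ctr <- c(d$x[k], d$y[k])
    if (d$rotates[k]) ctr <- .rot(ctr, phantom@insetAngle)
    paint(ctr, d$r[k], d$material[k], d$scale[k])
  }
  insetMask <- X^2 + Y^2 < 5.9^2
  lumps <- rasterizeLumpField(phantom@lumpField, gridSize, fov,
                              phantom@insetAngle)
  lumpMask <- insetMask & ch$iron == 0
  ch$water[lumpMask] <- ch$water[lumpMask] + lumps[lumpMask]
  if (phantom@signalPresent) {
    sig <- X^2 + Y^2 < 0.5^2
    ch$water[sig] <- phantom@signalAmplitude * 1.05
    ch$bone[sig] <- 0; ch$iron[sig] <- 0
  }
  ch$water[ch$water < 0] <- 0
  list(channels = ch, pixelSize = fov / gridSize, fov = fov)
}

#' View angles and detector positions of a geometry
#'
#' @param geom a [ProjectionGeometry-class].
#' @return `viewAngles`: radians over \eqn{[0, \pi)}; `detectorPositions`:
#'   signed detector coordinates s, cm, centered on the rotation axis.
#' @export
viewAngles <- function(geom) (seq_len(geom@nViews) - 1) * pi / geom@nViews

#' @rdname viewAngles
#' @export
detectorPositions <- function(geom)
  (seq_len(geom@nBins) - (geom@nBins + 1) / 2) * geom@binSpacing

#' Analytic parallel-beam sinograms of phantom primitives
#'
#' Closed-form Radon transforms: a disk of radius \eqn{R_0} centered at c
#' projects to the chord length \eqn{2\sqrt{R_0^2 - d^2}} with
#' \eqn{d = s - c\cdot(\cos\theta, \sin\theta)}; a Gaussian lump
#' \eqn{\mu_i e^{-\pi|r - r_i|^2 / w_i^2}} projects to
#' \eqn{\mu_i w_i e^{-\pi (s - r_i\cdot(\cos\theta,\sin\theta))^2 / w_i^2}}.
#'
#' @param center primitive center, cm (length 2).
#' @param radius disk radius, cm.
#' @param geom a [ProjectionGeometry-class].
#' @return nViews x nBins matrix of path lengths (cm), or cm-weighted
#'   amplitude for Gaussians.
#' @export
analyticDiskSinogram <- function(center, radius, geom) {
  th <- viewAngles(geom); s <- detectorPositions(geom)
  proj <- center[1] * cos(th) + center[2] * sin(th)
  d2 <- outer(proj, s, function(p, s) (s - p)^2)
  out <- radius^2 - d2
  out[out < 0] <- 0
  2 * sqrt(out)
}

#' @rdname analyticDiskSinogram
#' @param width Gaussian lump width \eqn{w_i}, cm.
#' @param amplitude lump amplitude \eqn{\mu_i} (any unit; carried through).
#' @export
analyticGaussianSinogram <- function(center, width, amplitude, geom) {
  th <- viewAngles(geom); s <- detectorPositions(geom)
  proj <- center[1] * cos(th) + center[2] * sin(th)
  amplitude * width * exp(-pi * outer(proj, s, function(p, s) (s - p)^2) /
                            width^2)
}

#' @rdname analyticDiskSinogram
#' @param lumpField a [LumpField-class].
#' @param angle rigid rotation of the lump centers, radians.
#' @export
analyticLumpSinogram <- function(lumpField, geom, angle = 0) {
  out <- matrix(0, geom@nViews, geom@nBins)
  for (i in seq_along(lumpField@widths))
    out <- out + analyticGaussianSinogram(
      .rot(lumpField@centers[i, ], angle), lumpField@widths[i],
      lumpField@amplitudes[i], geom)
  out
}

#' @rdname analyticDiskSinogram
#' @param phantom a [PhantomInstance-class].
#' @details `analyticIronTrace()` sums the analytic path lengths of all iron
#'   disks of a phantom: the exact metal trace, used as the segmentation
#'   oracle.
#' @export
analyticIronTrace <- function(phantom, geom) {
  d <- phantom@disks[phantom@disks$material == "iron", ]
  out <- matrix(0, geom@nViews, geom@nBins)
  for (k in seq_len(nrow(d))) {
    ctr <- c(d$x[k], d$y[k])
    if (d$rotates[k]) ctr <- .rot(ctr, phantom@insetAngle)
    out <- out + d$scale[k] * analyticDiskSinogram(ctr, d$r[k], geom)
  }
  out
}
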