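#' Filtered backprojection with a Ram-Lak filter
#'
#' Classical parallel-beam FBP: each view is convolved with the band-limited
#' ramp (Ram-Lak) kernel, realized exactly in the spatial domain
#' (\eqn{h(0) = 1/(4\tau^2)}, \eqn{h(n) = -1/(\pi^2 n^2 \tau^2)} for odd n,
#' zero for even n, \eqn{\tau} the detector spacing) and applied by FFT with
#' zero padding; the filtered views are backprojected with linear
#' interpolation. The output is in 1/cm. The operator is linear in the
#' sinogram.
#'
#' @param sino a [LogSinogram-class] (or bare nViews x nBins matrix plus
#'   `geom`).
#' @param outSize output image side, pixels.
#' @param geom required when `sino` is a bare matrix.
#' @param method provenance label stored in the result.
#' @param params provenance list stored in the result.
#' @param window optional reconstruction window `list(n =, x0 =, y0 =)`
#'   (pixels; cm coordinates of pixel (1,1)); the default reconstructs the
#'   full centered `outSize` grid. A window matching a centered crop
#'   reproduces that crop of the full reconstruction bit-identically.
#' @param supportRadius optional circular support, cm: pixels outside it
#'   are left at zero (the phantom fits in r = 12 cm; pixels inside the
#'   support are unaffected). Default `Inf` reconstructs the whole grid.
#' @return a [ReconImage-class].
#' @export
fbp <- function(sino, outSize = 256L, geom = NULL, method = "FBP",
                params = list(), window = NULL, supportRadius = Inf) {
  if (is(sino, "LogSinogram")) {
    geom <- geometry(sino)
    vals <- sinogramValues(sino)
  } else {
    if (is.null(geom)) stop("geom is required for a bare sinogram matrix")
    vals <- sino
  }
  if (!all(is.finite(range(vals)))) stop("sinogram must be finite")
  filt <- .ramLakFilter(vals, geom@binSpacing)
  px <- geom@fov / outSize
  img <- if (is.null(window))
    cpp_back_project(filt, as.integer(outSize), px, geom@binSpacing,
                     if (is.finite(supportRadius)) supportRadius else 0)
  else
    cpp_back_project_window(filt, as.integer(window$n), px,
                            geom@binSpacing, window$x0, window$y0)
  new("ReconImage", pixels = img, pixelSize = px,
      method = method, params = params)
}

# Ram-Lak filtering of all views (rows) via FFT with zero padding; view
# pairs are packed into the real and imaginary parts of one complex signal
# (the kernel is real, so linear filtering keeps the parts separate).
.ramLakFilter <- function(sino, tau) {
  nb <- ncol(sino)
  nv <- nrow(sino)
  pad <- 2^ceiling(log2(2 * nb))
  # exact space-domain band-limited ramp kernel
  idx <- c(0:(pad / 2), -(pad / 2 - 1):-1)
  h <- numeric(pad)
  h[idx == 0] <- 1 / (4 * tau^2)
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi^2 * idx[odd]^2 * tau^2)
  H <- Re(fft(h))
  nPair <- ceiling(nv / 2)
  P <- matrix(0 + 0i, pad, nPair)
  re <- t(sino[seq(1, nv, by = 2), , drop = FALSE])
  P[seq_len(nb), ] <- re
  imIdx <- seq(2, nv, by = 2)
  P[seq_len(nb), seq_along(imIdx)] <- P[seq_len(nb), seq_along(imIdx)] +
    1i * t(sino[imIdx, , drop = FALSE])
  F <- mvfft(P) * H
  w <- mvfft(F, inverse = TRUE)[seq_len(nb), , drop = FALSE] / pad
  out <- matrix(0, nv, nb)
  out[seq(1, nv, by = 2), ] <- t(Re(w))
  out[imIdx, ] <- t(Im(w[, seq_along(imIdx), drop = FALSE]))
  out * tau   # discrete convolution approximates the integral
}

#' Convert attenuation to Hounsfield units
#'
#' \eqn{HU = 1000 (\mu - \mu_{water}) / \mu_{water}} against an effective
#' water coefficient (see [muWaterEffective()]).
#'
#' @param image a [ReconImage-class] or bare matrix of attenuation, 1/cm.
#' @param muWaterEff effective water attenuation, 1/cm, positive.
#' @return matrix of HU values.
#' @export
muToHu <- function(image, muWaterEff) {
  if (muWaterEff <= 0) stop("muWaterEff must be positive")
  px <- if (is(image, "ReconImage")) pixels(image) else image
  1000 * (px - muWaterEff) / muWaterEff
}

#' Write a reconstructed image as float TIFF
#'
#' @param image a [ReconImage-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReconTIFF <- function(image, path) {
  stopifnot(is(image, "ReconImage"))
  tiff::writeTIFF(pixels(image) / max(abs(pixels(image)), 1e-12), path,
                  bits.per.sample = 32L)
  invisible(path)
}
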