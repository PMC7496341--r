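#' Sinogram-domain metal segmentation
#'
#' Flags every bin whose log-attenuation exceeds a fixed threshold; the
#' metal trace of strong attenuators stands far above tissue values at
#' calibration dose. The threshold is held fixed after calibration (see
#' [calibrateThresholds()]): segmentation failure away from the calibration
#' condition is deliberate, observable behaviour.
#'
#' @param sino a [LogSinogram-class].
#' @param threshold log-attenuation threshold.
#' @return logical nViews x nBins mask, `TRUE` = corrupted by metal.
#' @export
segmentSinogramMetal <- function(sino, threshold) {
  sinogramValues(sino) > threshold
}

#' Inpaint masked sinogram bins
#'
#' Per view (along the detector axis), each maximal masked run is replaced
#' by linear interpolation between its nearest unmasked neighbours; runs
#' touching a detector edge take the nearest unmasked value. Unmasked bins
#' are untouched.
#'
#' @param sino a [LogSinogram-class].
#' @param mask logical matrix, shape of the sinogram.
#' @return a [LogSinogram-class].
#' @export
inpaintTrace <- function(sino, mask) {
  vals <- sinogramValues(sino)
  stopifnot(all(dim(mask) == dim(vals)))
  if (!any(mask))
    return(sino)
  new("LogSinogram", values = cpp_inpaint_rows(vals, mask),
      I0 = sino@I0, s0 = sino@s0, geometry = geometry(sino))
}

#' Sinogram-inpainting MAR, sinogram-domain segmentation (MAR 1)
#'
#' Segments the metal trace directly on the log sinogram by thresholding,
#' inpaints it, and reconstructs with FBP.
#'
#' @param sino a [LogSinogram-class].
#' @param threshold log-attenuation segmentation threshold.
#' @param outSize output image side, pixels.
#' @param fbpImage optional precomputed plain FBP of `sino`; reused verbatim
#'   when the segmentation mask comes out empty (MAR 1 then has no effect).
#' @return a [ReconImage-class] with method `"MAR1"`.
#' @export
mar1 <- function(sino, threshold, outSize = 256L, fbpImage = NULL) {
  mask <- segmentSinogramMetal(sino, threshold)
  if (!any(mask) && !is.null(fbpImage)) {
    out <- fbpImage
    out@method <- "MAR1"
    out@params <- list(threshold = threshold, maskFraction = 0)
    return(out)
  }
  fbp(inpaintTrace(sino, mask), outSize, method = "MAR1",
      params = list(threshold = threshold, maskFraction = mean(mask)))
}

#' Image-domain metal segmentation
#'
#' Thresholds the reconstructed image in Hounsfield units.
#'
#' @param image a [ReconImage-class].
#' @param huThreshold HU threshold.
#' @param muWaterEff effective water attenuation for the HU conversion;
#'   defaults to the bundled 120 kVp spectrum's value.
#' @return logical image-shaped mask, `TRUE` = metal pixel.
#' @export
segmentImageMetal <- function(image, huThreshold,
                              muWaterEff = muWaterEffective(loadSpectrum())) {
  muToHu(image, muWaterEff) > huThreshold
}

#' Sinogram-inpainting MAR, image-domain segmentation (MAR 2)
#'
#' Reconstructs once with FBP, segments metal pixels in the image by HU
#' threshold, forward-projects the metal mask to find the corrupted
#' sinogram bins (any bin whose metal path length exceeds half a pixel),
#' inpaints those bins and reconstructs again.
#'
#' @param sino a [LogSinogram-class].
#' @param huThreshold HU segmentation threshold.
#' @param outSize output image side, pixels.
#' @param muWaterEff effective water attenuation for the HU conversion.
#' @param reinsertMetal logical; paste the segmented metal pixels back into
#'   the inpainted reconstruction (default off: plain replacement).
#' @param fbpImage optional precomputed plain FBP of `sino`, reused for the
#'   segmentation step.
#' @return a [ReconImage-class] with method `"MAR2"`.
#' @export
mar2 <- function(sino, huThreshold, outSize = 256L,
                 muWaterEff = muWaterEffective(loadSpectrum()),
                 reinsertMetal = FALSE, fbpImage = NULL) {
  geom <- geometry(sino)
  img0 <- if (is.null(fbpImage)) fbp(sino, outSize) else fbpImage
  maskImg <- segmentImageMetal(img0, huThreshold, muWaterEff)
  if (!any(maskImg)) {
    out <- img0
    out@method <- "MAR2"
    out@params <- list(huThreshold = huThreshold, maskFraction = 0)
    return(out)
  }
  trace <- maskToTrace(maskImg, geom, pixelSize(img0))
  out <- fbp(inpaintTrace(sino, trace), outSize, method = "MAR2",
             params = list(huThreshold = huThreshold,
                           maskFraction = mean(trace)))
  if (reinsertMetal) out@pixels[maskImg] <- img0@pixels[maskImg]
  out
}

#' Metal trace of an image-domain mask
#'
#' Helper exposing MAR 2's trace binarization: projects a binary metal
#' image mask (pixel-driven splatting, exploiting the mask's sparsity),
#' flags bins with more than half a pixel of metal path, and dilates the
#' trace by one detector bin — the customary safety margin that keeps
#' partial-volume fringe bins inside the replaced region.
#'
#' @param maskImg logical image mask.
#' @param geom a [ProjectionGeometry-class].
#' @param pixelSizeCm image pixel size, cm.
#' @return logical nViews x nBins trace mask.
#' @export
maskToTrace <- function(maskImg, geom, pixelSizeCm) {
  tr <- cpp_splat_project(maskImg, geom@nViews, geom@nBins,
                          geom@binSpacing, pixelSizeCm) > pixelSizeCm / 2
  nb <- ncol(tr)
  tr | cbind(tr[, -1, drop = FALSE], FALSE) |
    cbind(FALSE, tr[, -nb, drop = FALSE])
}
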