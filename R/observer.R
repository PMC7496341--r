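#' Extract a centered region of interest
#'
#' Crops an odd-sided square centered on the phantom origin and vectorizes
#' it row-major into the observation vector g. On even-sided images the
#' center pixel is the one just below-left of the exact origin (a fixed
#' half-pixel convention, applied identically to all images and to the
#' channel grid).
#'
#' @param image a [ReconImage-class] or bare square matrix.
#' @param roiSide ROI side, pixels; odd and no larger than the image.
#' @return numeric vector of length `roiSide^2`.
#' @examples
#' length(extractROI(matrix(0, 128, 128), 121))
#' @export
extractROI <- function(image, roiSide) {
  px <- if (is(image, "ReconImage")) pixels(image) else image
  n <- nrow(px)
  if (roiSide %% 2 == 0) stop("roiSide must be odd")
  if (roiSide > n) stop("ROI larger than image")
  ctr <- floor((n + 1) / 2)
  h <- (roiSide - 1) / 2
  sub <- px[(ctr - h):(ctr + h), (ctr - h):(ctr + h)]
  as.vector(t(sub))   # row-major
}

#' Build a dense difference-of-Gaussians channel bank
#'
#' Radially symmetric band-pass channels defined in spatial frequency
#' \eqn{\rho} (cycles/pixel) by
#' \deqn{C_j(\rho) = e^{-\frac{1}{2}(\rho / (Q\sigma_j))^2} -
#'       e^{-\frac{1}{2}(\rho / \sigma_j)^2}, \quad \sigma_j = \sigma_0
#'       \alpha^j,}
#' for j = 0..p-1. Every channel has zero DC response; the passband center
#' frequency grows geometrically with j. Spatial-domain channel images are
#' obtained by inverse FFT on the ROI grid, centered, and unit-normalized;
#' columns of U use the same row-major vectorization as [extractROI()].
#'
#' @param roiSide ROI side, pixels (odd).
#' @param p number of channels.
#' @param sigma0 base frequency scale, cycles/pixel.
#' @param alpha geometric scale ratio between successive channels.
#' @param Q bandwidth ratio of the two Gaussians.
#' @return a [ChannelBank-class].
#' @export
buildDDOGBank <- function(roiSide, p = 10L, sigma0 = 0.005, alpha = 1.4,
                          Q = 1.67) {
  if (p < 1) stop("p must be at least 1")
  n <- as.integer(roiSide)
  k <- seq_len(n) - 1
  f <- ifelse(k > n / 2, k - n, k) / n
  rho <- sqrt(outer(f^2, f^2, "+"))
  U <- matrix(0, n * n, p)
  h <- floor(n / 2)
  ord <- ((seq_len(n) - (h + 1)) %% n) + 1   # zero-lag pixel to the center
  shift <- function(m) m[ord, ord]
  for (j in seq_len(p)) {
    sj <- sigma0 * alpha^(j - 1)
    C <- exp(-0.5 * (rho / (Q * sj))^2) - exp(-0.5 * (rho / sj)^2)
    u <- Re(fft(C, inverse = TRUE)) / (n * n)
    u <- shift(u)
    U[, j] <- as.vector(t(u))
  }
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  new("ChannelBank", U = U, roiSide = n,
      params = list(p = p, sigma0 = sigma0, alpha = alpha, Q = Q))
}

#' DDOG radial frequency profile
#'
#' Evaluates channel j's frequency response \eqn{C_j(\rho)}; exposed for
#' inspection and for checking the passband ordering.
#'
#' @param bank a [ChannelBank-class].
#' @param j channel index, 1-based.
#' @param rho radial frequencies, cycles/pixel.
#' @return numeric vector of responses.
#' @export
ddogProfile <- function(bank, j, rho) {
  pr <- bank@params
  sj <- pr$sigma0 * pr$alpha^(j - 1)
  exp(-0.5 * (rho / (pr$Q * sj))^2) - exp(-0.5 * (rho / sj)^2)
}

#' Apply a channel bank to ROI ensembles
#'
#' Computes the channel output \eqn{v = U^T g} for each ROI.
#'
#' @param rois matrix with one ROI vector per row (n x q), or a single ROI
#'   vector; for the two-class case supply `roisAbsent` and `roisPresent`.
#' @param bank a [ChannelBank-class].
#' @return n x p matrix of channel outputs.
#' @export
channelize <- function(rois, bank) {
  if (is.vector(rois)) rois <- matrix(rois, nrow = 1)
  if (ncol(rois) != nrow(channelMatrix(bank)))
    stop("ROI length does not match the channel grid")
  rois %*% channelMatrix(bank)
}

#' Bundle two-class channel outputs
#'
#' @param roisAbsent,roisPresent ROI matrices (one ROI per row) for signal
#'   absent / present.
#' @param bank a [ChannelBank-class].
#' @return a [ChannelOutputs-class].
#' @export
channelizeClasses <- function(roisAbsent, roisPresent, bank) {
  new("ChannelOutputs", v1 = channelize(roisAbsent, bank),
      v2 = channelize(roisPresent, bank))
}

#' Train a channelized Hotelling observer
#'
#' Sample class means give \eqn{\Delta\mu = \mu_2 - \mu_1}; the pooled
#' covariance is the equal-weight average of the two class sample
#' covariances (each with n-1 denominators); the template solves
#' \eqn{\Sigma w = \Delta\mu}.
#'
#' @param outputs a [ChannelOutputs-class]; each class needs more than p
#'   training vectors.
#' @return a [CHOTemplate-class].
#' @export
trainCHO <- function(outputs) {
  v1 <- outputs@v1; v2 <- outputs@v2
  p <- ncol(v1)
  if (nrow(v1) <= p || nrow(v2) <= p)
    stop("each class needs more than p training vectors")
  dmu <- colMeans(v2) - colMeans(v1)
  sig <- (cov(v1) + cov(v2)) / 2
  w <- tryCatch(solve(sig, dmu), error = function(e)
    stop("pooled channel covariance is singular; use more training samples"))
  new("CHOTemplate", w = as.numeric(w), deltaMu = dmu, sigma = sig)
}

#' Apply a CHO template
#'
#' Test statistic \eqn{t = w^T v} per channel-output vector.
#'
#' @param template a [CHOTemplate-class] (or bare numeric template vector).
#' @param v matrix of channel outputs (one per row) or a single vector.
#' @return numeric vector of test statistics.
#' @export
applyTemplate <- function(template, v) {
  w <- if (is(template, "CHOTemplate")) template@w else template
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  if (ncol(v) != length(w)) stop("dimension mismatch")
  as.numeric(v %*% w)
}

#' Observer SNR from class test statistics
#'
#' \deqn{SNR^2 = \frac{|\bar t_1 - \bar t_2|^2}
#'       {\frac{1}{2}(\sigma_{t1}^2 + \sigma_{t2}^2)}}
#' with sample means and variances.
#'
#' @param t1,t2 test statistics for the two classes (>= 2 values each).
#' @return nonnegative SNR.
#' @export
snrFromStatistics <- function(t1, t2) {
  if (length(t1) < 2 || length(t2) < 2)
    stop("each class needs at least 2 test statistics")
  pooled <- (var(t1) + var(t2)) / 2
  if (pooled <= 0) stop("zero pooled variance")
  abs(mean(t1) - mean(t2)) / sqrt(pooled)
}

#' Binormal AUC from SNR
#'
#' For Gaussian test statistics, \eqn{AUC = \Phi(SNR / \sqrt{2})}.
#'
#' @param snr nonnegative observer SNR.
#' @return AUC in [0.5, 1].
#' @export
aucBinormal <- function(snr) {
  stopifnot(all(snr >= 0))
  pnorm(snr / sqrt(2))
}

#' Empirical (Mann-Whitney) AUC
#'
#' Fraction of class pairs with \eqn{t_{2j} > t_{1i}}, ties counted one
#' half; computed via midranks. The rank-statistic oracle for the binormal
#' formula.
#'
#' @param t1 test statistics, signal absent.
#' @param t2 test statistics, signal present.
#' @return AUC in [0, 1].
#' @export
aucEmpirical <- function(t1, t2) {
  n1 <- as.numeric(length(t1)); n2 <- as.numeric(length(t2))
  if (n1 == 0 || n2 == 0) stop("both classes must be nonempty")
  r <- rank(c(t1, t2))
  (sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}
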