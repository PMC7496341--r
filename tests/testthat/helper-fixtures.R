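# Shared test fixtures, all built in code.

# small geometry for cheap pipeline tests (still >= 180 views)
tinyGeometry <- function(nBins = 65L) projectionGeometry(180L, nBins, 26)

# a mid-size geometry matching the scaled study detector
testGeometry <- function() projectionGeometry(360L, 729L, 26)

# synthetic two-class Gaussian channel outputs with a designed template:
# class means 0 and dmu, shared covariance sigma
gaussianOutputs <- function(n, dmu, sigma, seed = 1) {
  p <- length(dmu)
  set.seed(seed)
  L <- chol(sigma)
  v1 <- matrix(rnorm(n * p), n, p) %*% L
  v2 <- sweep(matrix(rnorm(n * p), n, p) %*% L, 2, dmu, "+")
  new("ChannelOutputs", v1 = v1, v2 = v2)
}

# designed 10-dim covariance (well conditioned, non-diagonal)
designedSigma <- function(p = 10) {
  s <- outer(seq_len(p), seq_len(p), function(i, j) 0.4^abs(i - j))
  diag(p) * 0.5 + s
}

# analytic SNR and AUC of the designed Gaussian task
analyticSNR <- function(dmu, sigma) sqrt(drop(t(dmu) %*% solve(sigma, dmu)))

# scale dmu so the analytic AUC hits a target value
dmuForAUC <- function(auc, sigma, direction = NULL) {
  p <- nrow(sigma)
  if (is.null(direction)) direction <- rep(1, p)
  snrTarget <- sqrt(2) * qnorm(auc)
  direction * snrTarget / analyticSNR(direction, sigma)
}
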