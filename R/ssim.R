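# 3D structural similarity with a uniform cubic window.
#
# Local means/variances/covariances are computed at every valid window
# position with a separable sliding-sum filter; the reported value is the
# mean local SSIM.  ssimStats() keeps the per-window statistics so the
# analytic gradient with respect to the first argument can be formed for
# the fusion loss.

ssimStats <- function(x, y, win = 7L, k1 = 0.01, k2 = 0.03, L = 1) {
  if (!all(dim(x) == dim(y))) stop("ssim3d: inputs must share a shape")
  if (any(dim(x) < win)) stop("ssim3d: window larger than volume")
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  d <- dim(x)
  mux <- cpp_boxfilter_valid(x, d, win)
  muy <- cpp_boxfilter_valid(y, d, win)
  sxx <- cpp_boxfilter_valid(x * x, d, win) - mux^2
  syy <- cpp_boxfilter_valid(y * y, d, win) - muy^2
  sxy <- cpp_boxfilter_valid(x * y, d, win) - mux * muy
  a1 <- 2 * mux * muy + C1
  a2 <- 2 * sxy + C2
  b1 <- mux^2 + muy^2 + C1
  b2 <- sxx + syy + C2
  s <- (a1 * a2) / (b1 * b2)
  list(mssim = mean(s), x = x, y = y, mux = mux, muy = muy,
       a1 = a1, a2 = a2, b1 = b1, b2 = b2, win = win, dims = d)
}

# d mean(S) / dx, propagated through the local means/variances/covariance
ssimGradX <- function(st) {
  with(st, {
    nwin <- length(a1)
    dS_dmux <- 2 * muy * a2 / (b1 * b2) - 2 * mux * a1 * a2 / (b1^2 * b2)
    dS_dsxx <- -a1 * a2 / (b1 * b2^2)
    dS_dsxy <- 2 * a1 / (b1 * b2)
    g <- cpp_boxfilter_adjoint(dS_dmux, dims, win) +
      2 * x * cpp_boxfilter_adjoint(dS_dsxx, dims, win) -
      2 * cpp_boxfilter_adjoint(dS_dsxx * mux, dims, win) +
      y * cpp_boxfilter_adjoint(dS_dsxy, dims, win) -
      cpp_boxfilter_adjoint(dS_dsxy * muy, dims, win)
    g / nwin
  })
}

#' 3D structural similarity index
#'
#' Mean local SSIM between two volumes of identical shape, computed with a
#' uniform cubic window at every valid position.  Symmetric in its
#' arguments and equal to 1 when the volumes are identical.
#'
#' @param x,y numeric 3D arrays of identical dimensions.
#' @param win odd window side length in voxels (default 7).
#' @param k1,k2 stabilizing constants of the luminance and contrast terms.
#' @param L dynamic range of the data (1 for volumes scaled to \[0, 1\]).
#' @return scalar SSIM value in \[-1, 1\].
#' @examples
#' x <- array(runif(12^3), dim = c(12, 12, 12))
#' ssim3d(x, x)  # 1
#' @export
ssim3d <- function(x, y, win = 7L, k1 = 0.01, k2 = 0.03, L = 1) {
  ssimStats(x, y, win = win, k1 = k1, k2 = k2, L = L)$mssim
}
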