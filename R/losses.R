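# Segmentation losses and the learning-rate schedule.

#' Soft Dice loss
#'
#' \code{1 - 2 * sum(p g) / (sum(p^2) + sum(g^2) + eps)} over all voxels.
#'
#' @param p prediction array/vector with values in \[0, 1\].
#' @param g binary ground-truth array/vector of the same length.
#' @param eps smoothing constant protecting the denominator.
#' @return scalar loss in \[0, 1\] (up to the smoothing).
#' @examples
#' diceLoss(c(1, 0), c(1, 1))  # 1 - 2/3
#' @export
diceLoss <- function(p, g, eps = 1e-5) {
  if (length(p) != length(g)) stop("prediction and target sizes differ")
  1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2) + eps)
}

#' Binary cross-entropy loss (mean over voxels)
#'
#' Predictions are clipped away from 0 and 1 before taking logarithms.
#'
#' @param p prediction array/vector with values in \[0, 1\].
#' @param g binary ground-truth of the same length.
#' @param clip clipping margin for the probabilities.
#' @return scalar loss, non-negative.
#' @examples
#' bceLoss(rep(0.5, 8), rbinom(8, 1, 0.5))  # log(2)
#' @export
bceLoss <- function(p, g, clip = 1e-7) {
  if (length(p) != length(g)) stop("prediction and target sizes differ")
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Region-based segmentation loss
#'
#' Sum over the stage's output regions of Dice plus lambda times BCE.
#'
#' @param pRegions named list of per-region prediction arrays.
#' @param gRegions named list of matching binary target arrays.
#' @param cfg a \linkS4class{SegLossConfig}.
#' @return scalar loss.
#' @export
segLoss <- function(pRegions, gRegions, cfg = segLossConfig()) {
  stopifnot(is(cfg, "SegLossConfig"))
  if (length(pRegions) != length(gRegions)) {
    stop("prediction and target region lists differ in length")
  }
  total <- 0
  for (i in seq_along(pRegions)) {
    total <- total + diceLoss(pRegions[[i]], gRegions[[i]], cfg@epsilon) +
      cfg@lambda * bceLoss(pRegions[[i]], gRegions[[i]])
  }
  total
}

#' Polynomially decayed learning rate
#'
#' \code{l0 * (1 - i/N)^0.9} for epoch counter i of N total epochs.
#'
#' @param i epoch counter (0-based).
#' @param nEpochs total number of epochs N.
#' @param l0 initial learning rate (default 1e-4).
#' @param power decay exponent (default 0.9).
#' @return learning rate for epoch i.
#' @examples
#' lrSchedule(0, 300)    # 1e-4
#' lrSchedule(150, 300)  # ~5.359e-5
#' lrSchedule(300, 300)  # 0
#' @export
lrSchedule <- function(i, nEpochs, l0 = 1e-4, power = 0.9) {
  l0 * (1 - i / nEpochs)^power
}
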