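# Pixel-level fusion network.
#
# Two branches (one per source modality), each a 3x3x3 convolution
# followed by a 3D residual block; the branch features are concatenated,
# passed through a residual block at doubled width, reduced back to one
# channel by two further convolutions and squashed by a sigmoid into a
# voxelwise weight mask M.  The fused volume is the convex combination
# F = M * S1 + (1 - M) * S2, which keeps every fused voxel inside the
# per-voxel source envelope and in particular keeps zero background
# exactly zero.  All convolutions are stride 1, padding 1, so the
# spatial shape is preserved end to end.

PAIRING_SOURCES <- list(
  "t2+flair"  = c("t2", "flair"),      # S1 = t2
  "t1c+t2"    = c("t1c", "t2"),        # S1 = t1c
  "t1c+flair" = c("t1c", "flair"))

PAIRING_FUSED_NAME <- c("t2+flair" = "t2-flair",
                        "t1c+t2" = "t1c-t2",
                        "t1c+flair" = "t1c-flair")

#' Initialize a pixel-level fusion network
#'
#' @param pairing the modality pairing this network will fuse.
#' @param channels branch feature width (default 32).
#' @param seed RNG seed for the weight initialization.
#' @param lossConfig a \linkS4class{FusionLossConfig}; defaults follow
#'   the pairing.
#' @return an untrained \linkS4class{PifNet}.
#' @export
pifnetInit <- function(pairing = "t2+flair", channels = 32L, seed = 1L,
                       lossConfig = fusionLossConfig(pairing)) {
  pairing <- match.arg(pairing, names(PAIRING_SOURCES))
  ch <- as.integer(channels)
  params <- withSeed(seed, function() {
    resInit <- function(c) list(c1 = convInit(3L, c, c), c2 = convInit(3L, c, c))
    list(
      branch1 = list(conv = convInit(3L, 1L, ch), res = resInit(ch)),
      branch2 = list(conv = convInit(3L, 1L, ch), res = resInit(ch)),
      res5 = resInit(2L * ch),
      conv6 = convInit(3L, 2L * ch, ch),
      conv7 = convInit(3L, ch, 1L))
  })
  new("PifNet", pairing = pairing, channels = ch, params = params,
      lossConfig = lossConfig, history = numeric(0))
}

# residual block: conv-ReLU-conv, skip addition, ReLU
agRes3d <- function(x, p) {
  h <- agRelu(agConv3d(x, p$c1$w, p$c1$b))
  h <- agConv3d(h, p$c2$w, p$c2$b)
  agRelu(agAdd(h, x))
}

pifnetMaskNode <- function(net, s1, s2) {
  p <- net@params
  asIn <- function(x) {
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    agConst(x)
  }
  b1 <- agRes3d(agRelu(agConv3d(asIn(s1), p$branch1$conv$w, p$branch1$conv$b)),
                p$branch1$res)
  b2 <- agRes3d(agRelu(agConv3d(asIn(s2), p$branch2$conv$w, p$branch2$conv$b)),
                p$branch2$res)
  h <- agRes3d(agConcatC(b1, b2), p$res5)
  h <- agConv3d(h, p$conv6$w, p$conv6$b)
  h <- agConv3d(h, p$conv7$w, p$conv7$b)
  agSigmoid(h)
}

#' Forward pass of the fusion network
#'
#' @param net a \linkS4class{PifNet}.
#' @param s1,s2 numeric 3D arrays: the two source volumes (S1 is the
#'   branch-1 source; for the T1c-led pairings that is the T1c volume).
#' @return list with the weight mask \code{mask} (values in \[0, 1\]) and
#'   the fused volume \code{fused}, both with the input shape.
#' @export
pifnetForward <- function(net, s1, s2) {
  if (!all(dim(s1) == dim(s2))) stop("source volumes must share a shape")
  m <- pifnetMaskNode(net, s1, s2)
  mask <- drop(m$value)
  dim(mask) <- dim(s1)
  list(mask = mask, fused = mask * s1 + (1 - mask) * s2)
}

#' Pixel term of the fusion loss
#'
#' Summed squared (Frobenius) error of the fused volume against both
#' sources, with weight beta on the second source.
#'
#' @param fused fused volume (numeric array).
#' @param s1,s2 source volumes of the same shape.
#' @param beta trade-off weight on the second source.
#' @return scalar loss, non-negative.
#' @export
pixelLoss <- function(fused, s1, s2, beta = 1) {
  sum((fused - s1)^2) + beta * sum((fused - s2)^2)
}

#' Structural term of the fusion loss
#'
#' \code{gamma * (1 - SSIM(F, S1)) + (1 - SSIM(F, S2))} with the 3D SSIM
#' of \code{\link{ssim3d}}.
#'
#' @param fused fused volume (numeric 3D array).
#' @param s1,s2 source volumes of the same shape.
#' @param gamma trade-off weight on the first source.
#' @param win,k1,k2 SSIM window and stabilizers.
#' @return scalar loss, non-negative.
#' @export
ssimLoss <- function(fused, s1, s2, gamma = 1, win = 7L, k1 = 0.01,
                     k2 = 0.03) {
  gamma * (1 - ssim3d(fused, s1, win, k1, k2)) +
    (1 - ssim3d(fused, s2, win, k1, k2))
}

#' Composite fusion loss
#'
#' L_pixel is the summed squared error against both sources with weight
#' beta on the second; L_ssim penalizes structural dissimilarity with
#' weight gamma on the first source; the total is
#' L = L_pixel + alpha * L_ssim.
#'
#' @param fused fused volume (numeric 3D array).
#' @param s1,s2 source volumes.
#' @param cfg a \linkS4class{FusionLossConfig}.
#' @return named list with \code{pif}, \code{pixel} and \code{ssim} terms.
#' @export
fusionLoss <- function(fused, s1, s2, cfg) {
  stopifnot(is(cfg, "FusionLossConfig"))
  lpix <- pixelLoss(fused, s1, s2, cfg@beta)
  lssim <- ssimLoss(fused, s1, s2, cfg@gamma, cfg@ssimWindow, cfg@k1, cfg@k2)
  list(pif = lpix + cfg@alpha * lssim, pixel = lpix, ssim = lssim)
}

# scale a volume to [0, 1] by its own range (fusion operates on bounded
# intensities so the SSIM constants are meaningful)
minMaxScale <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(x * 0)
  (x - lo) / (hi - lo)
}

# sliding-window training patches with a minimum tumor-agnostic content
# requirement (>= 5% non-zero voxels)
slidingPatches <- function(x, size, stride = size) {
  d <- dim(x)
  starts <- lapply(1:3, function(a) {
    unique(c(seq(0L, d[a] - size[a], by = stride[a]), d[a] - size[a]))
  })
  out <- list()
  for (o3 in starts[[3]]) for (o2 in starts[[2]]) for (o1 in starts[[1]]) {
    out[[length(out) + 1L]] <- WindowSpec(c(o1, o2, o3), size)
  }
  out
}

#' Train a pixel-level fusion network
#'
#' Extracts sliding-window patches from the pairing's source modalities
#' (min-max scaled to \[0, 1\] per volume; patches with fewer than 5\%
#' non-zero voxels are skipped), then minimizes the composite fusion
#' loss with Adam at a fixed learning rate.
#'
#' @param net an initialized \linkS4class{PifNet}.
#' @param cases list of \linkS4class{MultimodalCase}s containing both
#'   source modalities of the pairing.
#' @param steps number of optimization steps.
#' @param patchSize cubic patch side (default 16 for desk-scale work;
#'   80 reproduces the full-scale protocol).
#' @param lr Adam learning rate (default 1e-4, fixed).
#' @param seed RNG seed for patch shuffling.
#' @return the trained \linkS4class{PifNet} with its loss history.
#' @export
trainPifNet <- function(net, cases, steps = 200L, patchSize = 16L,
                        lr = 1e-4, seed = 1L) {
  stopifnot(is(net, "PifNet"))
  if (length(cases) == 0L) stop("empty training dataset")
  src <- PAIRING_SOURCES[[net@pairing]]
  cfg <- net@lossConfig
  pat <- list()
  for (case in cases) {
    s1 <- minMaxScale(volData(getVolume(case, src[1])))
    s2 <- minMaxScale(volData(getVolume(case, src[2])))
    size <- pmin(rep(as.integer(patchSize), 3L), dim(s1))
    for (ws in slidingPatches(s1, size)) {
      p1 <- cropWindow(s1, ws)
      if (mean(p1 != 0) < 0.05) next  # all-background patches are uninformative
      pat[[length(pat) + 1L]] <- list(s1 = p1, s2 = cropWindow(s2, ws))
    }
  }
  if (length(pat) == 0L) stop("no usable training patches")
  opt <- adamInit(net@params, lr = lr)
  hist <- numeric(steps)
  withSeed(seed, function() {
    order <- sample(rep_len(seq_along(pat), steps))
    for (step in seq_len(steps)) {
      p <- pat[[order[step]]]
      agZeroGrad(net@params)
      m <- pifnetMaskNode(net, p$s1, p$s2)
      f <- agFuseMask(m, p$s1, p$s2)
      lpix <- agPixelLoss(f, p$s1, p$s2, cfg@beta)
      ss1 <- agSsim(f, p$s1, cfg@ssimWindow, cfg@k1, cfg@k2)
      ss2 <- agSsim(f, p$s2, cfg@ssimWindow, cfg@k1, cfg@k2)
      loss <- agScalarComb(list(lpix, ss1, ss2),
                           c(1, -cfg@alpha * cfg@gamma, -cfg@alpha),
                           const = cfg@alpha * (cfg@gamma + 1))
      agBackward(loss)
      opt <<- adamStep(opt)
      hist[step] <<- loss$value
    }
  })
  net@history <- c(net@history, hist)
  net
}

#' Add fused modalities to a case
#'
#' Applies trained fusion networks to produce the stage-1 modality
#' ("t2-flair") and/or the stage-2 modalities ("t1c-t2", "t1c-flair").
#' Sources are min-max scaled to \[0, 1\] before fusion; the fused
#' volumes are stored on that scale (the segmentation pipeline z-score
#' normalizes every modality, which is invariant to the scale choice).
#'
#' @param case a \linkS4class{MultimodalCase}.
#' @param nets named list of trained \linkS4class{PifNet}s, keyed by
#'   pairing.
#' @param pairings pairings to apply (default: all present in
#'   \code{nets}).
#' @return the case with the fused volumes added; sources untouched.
#' @export
fuseCase <- function(case, nets, pairings = names(nets)) {
  stopifnot(is(case, "MultimodalCase"))
  for (pr in pairings) {
    if (!pr %in% names(nets)) stop(sprintf("no trained fusion network for pairing '%s'", pr))
    net <- nets[[pr]]
    src <- PAIRING_SOURCES[[pr]]
    s1 <- minMaxScale(volData(getVolume(case, src[1])))
    s2 <- minMaxScale(volData(getVolume(case, src[2])))
    fused <- pifnetForward(net, s1, s2)$fused
    case@volumes[[PAIRING_FUSED_NAME[[pr]]]] <-
      BrainVolume(fused, volAffine(getVolume(case, src[1])))
  }
  methods::validObject(case)
  case
}
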