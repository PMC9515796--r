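# Two-stage training and inference.
#
# Stage 1 segments the whole tumor from {t2, flair, t2-flair}; its
# binarized output locates the stage-2 window, in which stage 2 segments
# tumor core and enhancing tumor from all six modalities.  Training is
# region-based: each output head is optimized against its overlapping
# binary target with Dice + lambda * BCE, under the polynomial
# learning-rate decay and flip/intensity augmentation.

# z-score normalize every listed modality of a case, returning arrays
normalizedInputs <- function(case, modalities) {
  lapply(modalities, function(m)
    volData(zscoreNormalize(getVolume(case, m))))
}

# random flip (shared across modalities and targets) plus per-modality
# intensity shift/scale
augmentSample <- function(inputs, targets) {
  flips <- stats::runif(3) < 0.5
  flipArr <- function(x) {
    if (flips[1]) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    if (flips[2]) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    if (flips[3]) x <- x[, , rev(seq_len(dim(x)[3])), drop = FALSE]
    x
  }
  inputs <- lapply(inputs, function(x) {
    x <- flipArr(x)
    sdv <- stats::sd(x[x != 0])
    if (!is.finite(sdv)) sdv <- 0
    shift <- stats::runif(1, -0.1, 0.1) * sdv
    scale <- stats::runif(1, 0.9, 1.1)
    y <- x * scale
    y[x != 0] <- y[x != 0] + shift
    y
  })
  targets <- lapply(targets, flipArr)
  list(inputs = inputs, targets = targets)
}

# crop the training sample for a stage: random window for stage 1, the
# maximum-tumor window (on the ground-truth whole tumor) for stage 2;
# volumes smaller than the crop are zero-padded symmetrically
stageTrainingCrop <- function(inputs, regions, cfg) {
  d <- dim(inputs[[1]])
  size <- pmin(cfg@cropSize, d)
  if (cfg@stage == 1L) {
    o <- vapply(1:3, function(a) {
      if (d[a] == size[a]) 0L else sample.int(d[a] - size[a] + 1L, 1L) - 1L
    }, integer(1))
    ws <- WindowSpec(o, size)
  } else {
    ws <- maxTumorWindow(regions$wt, size)
  }
  crop <- function(x) cropWindow(x, ws)
  padded <- function(x) {
    if (all(dim(x) == cfg@cropSize)) x else padToShape(x, cfg@cropSize)$data
  }
  list(inputs = lapply(lapply(inputs, crop), padded),
       targets = lapply(lapply(regions, crop), padded))
}

#' Train one segmentation stage
#'
#' @param cases list of labeled \linkS4class{MultimodalCase}s already
#'   carrying the fused modalities the stage consumes (see
#'   \code{\link{fuseCase}}).
#' @param cfg a \linkS4class{StageConfig}.
#' @param lossCfg a \linkS4class{SegLossConfig}.
#' @param epochs total epochs N of the decay schedule.
#' @param l0 initial learning rate (default 1e-4).
#' @param seed RNG seed for initialization, shuffling and augmentation.
#' @param augment apply flip/intensity augmentation (default TRUE).
#' @param model optionally continue training an existing
#'   \linkS4class{StageModel}.
#' @return the trained \linkS4class{StageModel} with per-epoch losses in
#'   its history.
#' @export
trainStage <- function(cases, cfg, lossCfg = segLossConfig(), epochs = 30L,
                       l0 = 1e-4, seed = 1L, augment = TRUE, model = NULL) {
  if (length(cases) == 0L) stop("empty training dataset")
  if (any(vapply(cases, function(cs) is.null(caseLabel(cs)), logical(1)))) {
    stop("all training cases must carry a label volume")
  }
  if (is.null(model)) model <- buildStageNet(cfg, seed = seed)
  # pre-normalize once; crops/augmentation stay stochastic per epoch
  prepped <- lapply(cases, function(cs) {
    rm <- labelsToRegions(caseLabel(cs))
    regions <- lapply(cfg@outputRegions, function(r) regionMask(rm, r))
    names(regions) <- cfg@outputRegions
    regions$wt <- regionMask(rm, "wt")  # stage-2 window localization
    list(inputs = normalizedInputs(cs, cfg@inputModalities),
         regions = regions)
  })
  opt <- adamInit(model@params, lr = l0)
  hist <- numeric(epochs)
  withSeed(seed + 7L, function() {
    for (ep in seq_len(epochs)) {
      lr <- lrSchedule(ep - 1L, epochs, l0)
      losses <- numeric(0)
      for (ci in sample(seq_along(prepped))) {
        smp <- prepped[[ci]]
        cr <- stageTrainingCrop(smp$inputs, smp$regions, cfg)
        targets <- cr$targets[cfg@outputRegions]
        inputs <- cr$inputs
        if (augment) {
          aug <- augmentSample(inputs, targets)
          inputs <- aug$inputs
          targets <- aug$targets
        }
        agZeroGrad(model@params)
        out <- stageForwardNode(model, inputs)
        terms <- list()
        coefs <- numeric(0)
        for (r in cfg@outputRegions) {
          terms <- c(terms, list(agDiceLoss(out$probs[[r]], targets[[r]],
                                            lossCfg@epsilon),
                                 agBceLoss(out$probs[[r]], targets[[r]])))
          coefs <- c(coefs, 1, lossCfg@lambda)
        }
        loss <- agScalarComb(terms, coefs)
        agBackward(loss)
        opt <<- adamStep(opt, lr = lr)
        losses <- c(losses, loss$value)
      }
      hist[ep] <<- mean(losses)
    }
  })
  model@history <- c(model@history, hist)
  model
}

# pad a volume so every extent divides 2^(depth-1), run the model, crop
# the probabilities back; optionally in tiles
applyStage <- function(model, case, window = NULL, tile = NULL) {
  cfg <- model@config
  inputs <- normalizedInputs(case, cfg@inputModalities)
  if (!is.null(window)) {
    inputs <- lapply(inputs, cropWindow, ws = window)
  }
  d <- dim(inputs[[1]])
  if (!is.null(tile) && any(tile < d)) {
    size <- pmin(as.integer(tile), d)
    probs <- lapply(cfg@outputRegions, function(r) array(0, dim = d))
    names(probs) <- cfg@outputRegions
    for (ws in slidingPatches(inputs[[1]], size)) {
      sub <- lapply(inputs, cropWindow, ws = ws)
      pr <- stageForward(model, sub)
      o <- ws@origin
      for (r in cfg@outputRegions) {
        probs[[r]][o[1] + seq_len(size[1]), o[2] + seq_len(size[2]),
                   o[3] + seq_len(size[3])] <- pr[[r]]
      }
    }
    return(probs)
  }
  mult <- 2L^(cfg@depth - 1L)
  target <- as.integer(ceiling(d / mult) * mult)
  if (any(target != d)) {
    padded <- lapply(inputs, function(x) padToShape(x, target))
    off <- padded[[1]]$offset
    pr <- stageForward(model, lapply(padded, `[[`, "data"))
    lapply(pr, function(p) cropWindow(p, WindowSpec(off, d)))
  } else {
    stageForward(model, inputs)
  }
}

#' Replace small enhancing-tumor predictions by necrosis
#'
#' When the predicted enhancing tumor has fewer voxels than the
#' threshold it is considered a false positive and relabeled as
#' NCR/NET (label 1); at or above the threshold the volume is unchanged.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param threshold minimum enhancing-tumor voxel count (default 500).
#' @return the post-processed \linkS4class{LabelVolume}.
#' @export
postprocessEt <- function(labels, threshold = 500L) {
  stopifnot(is(labels, "LabelVolume"))
  x <- labels@data
  nEt <- sum(x == 4L)
  if (nEt > 0 && nEt < threshold) {
    x[x == 4L] <- 1L
    return(LabelVolume(x, labels@affine))
  }
  labels
}

#' Two-stage prediction for one case
#'
#' Fuses the stage-1 modality, segments the whole tumor, locates the
#' stage-2 window on the predicted tumor, fuses the stage-2 modalities
#' and segments core and enhancing tumor inside the window.  Nesting is
#' enforced by intersection (tc within wt, et within tc); whole-tumor
#' voxels not claimed by the core become edema.
#'
#' @param case a \linkS4class{MultimodalCase} with the four source
#'   modalities.
#' @param stage1,stage2 trained \linkS4class{StageModel}s, or functions
#'   \code{function(case, window)} returning named per-region
#'   probability arrays (used to stub a stage, e.g. in pipeline tests).
#' @param fusionNets named list of trained \linkS4class{PifNet}s keyed
#'   by pairing ("t2+flair", "t1c+t2", "t1c+flair").
#' @param threshold binarization threshold on the sigmoid outputs.
#' @param window2 stage-2 window extents (default: the stage-2 crop size,
#'   limited by the volume shape).
#' @param tile optional tile extents for stage-1 inference on volumes
#'   too large for a single forward pass.
#' @return list with the assembled \linkS4class{LabelVolume}
#'   (\code{labels}), the \linkS4class{RegionMasks} (\code{regions}),
#'   the stage-2 \linkS4class{WindowSpec} (\code{window}) and the raw
#'   probability arrays (\code{probs}).
#' @export
predictCase <- function(case, stage1, stage2, fusionNets,
                        threshold = 0.5, window2 = NULL, tile = NULL) {
  stopifnot(is(case, "MultimodalCase"))
  d <- dim(volData(case@volumes[[1]]))
  runStage <- function(model, fusedCase, window) {
    if (is.function(model)) model(fusedCase, window)
    else applyStage(model, fusedCase, window = window,
                    tile = if (is.null(window)) tile else NULL)
  }
  # stage 1: whole tumor on the full volume
  c1 <- if (is.function(stage1)) case else fuseCase(case, fusionNets, "t2+flair")
  p1 <- runStage(stage1, c1, NULL)
  wt <- array(as.numeric(p1$wt >= threshold), dim = d)
  # stage 2 window from the predicted whole tumor (origin default on empty)
  if (is.null(window2)) {
    size2 <- if (is.function(stage2)) d else pmin(stage2@config@cropSize, d)
  } else {
    size2 <- pmin(as.integer(window2), d)
  }
  ws <- maxTumorWindow(wt, size2)
  c2 <- if (is.function(stage2)) {
    case
  } else {
    fuseCase(case, fusionNets, c("t1c+t2", "t1c+flair"))
  }
  p2 <- runStage(stage2, c2, ws)
  embed <- function(x) {
    full <- array(0, dim = d)
    o <- ws@origin
    full[o[1] + seq_len(size2[1]), o[2] + seq_len(size2[2]),
         o[3] + seq_len(size2[3])] <- x
    full
  }
  tc <- embed(as.numeric(p2$tc >= threshold))
  et <- embed(as.numeric(p2$et >= threshold))
  # enforce nesting by intersection
  tc <- tc * wt
  et <- et * tc
  regions <- RegionMasks(wt = wt, tc = tc, et = et)
  labels <- regionsToLabels(regions, affine = volAffine(case@volumes[[1]]))
  list(labels = labels, regions = regions, window = ws,
       probs = list(wt = p1$wt, tc = p2$tc, et = p2$et))
}
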