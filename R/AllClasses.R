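# S4 classes for the multimodal segmentation framework.

BRATS_LABELS <- c(0L, 1L, 2L, 4L)
SOURCE_MODALITIES <- c("t1", "t1c", "t2", "flair")
FUSED_MODALITIES <- c("t2-flair", "t1c-t2", "t1c-flair")
REGION_NAMES <- c("wt", "tc", "et")

#' A single 3D intensity volume with its spatial transform
#'
#' @slot data numeric 3D array, indexed (depth, height, width).
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix"))

setValidity("BrainVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d <= 0L)) return("all extents must be positive")
  if (!all(is.finite(object@data))) return("data must be finite")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Construct a BrainVolume
#' @param data numeric 3D array (depth x height x width).
#' @param affine 4x4 voxel-to-world matrix (identity by default).
#' @return a \linkS4class{BrainVolume}.
#' @export
BrainVolume <- function(data, affine = diag(4)) {
  new("BrainVolume", data = data, affine = affine)
}

#' Integer tumor label volume in BraTS coding
#'
#' Voxels take values 0 (background), 1 (necrosis / non-enhancing tumor),
#' 2 (peritumoral edema) or 4 (enhancing tumor).
#' @export
setClass("LabelVolume", contains = "BrainVolume")

setValidity("LabelVolume", function(object) {
  vals <- unique(as.vector(object@data))
  if (!all(vals %in% BRATS_LABELS)) {
    return(sprintf("label values outside {0,1,2,4}: %s",
                   paste(setdiff(vals, BRATS_LABELS), collapse = ", ")))
  }
  TRUE
})

#' Construct a LabelVolume
#' @param data integer-valued 3D array over {0, 1, 2, 4}.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(data, affine = diag(4)) {
  new("LabelVolume", data = data, affine = affine)
}

#' One subject's co-registered multimodal volumes
#'
#' @slot caseId subject identifier, used in file names.
#' @slot volumes named list of \linkS4class{BrainVolume}s; names are
#'   modality identifiers ("t1", "t1c", "t2", "flair" and the fused
#'   "t2-flair", "t1c-t2", "t1c-flair").
#' @slot label a \linkS4class{LabelVolume} or NULL.
#' @export
setClass("MultimodalCase",
  representation(caseId = "character", volumes = "list", label = "ANY"))

setValidity("MultimodalCase", function(object) {
  if (length(object@volumes) == 0L) return("at least one volume required")
  nm <- names(object@volumes)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    return("volumes must have unique non-empty modality names")
  }
  if (!all(vapply(object@volumes, is, logical(1), "BrainVolume"))) {
    return("all volumes must be BrainVolume objects")
  }
  dims <- lapply(object@volumes, function(v) dim(v@data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    return("all volumes must share one shape")
  }
  if (!is.null(object@label)) {
    if (!is(object@label, "LabelVolume")) return("label must be a LabelVolume")
    if (!identical(dim(object@label@data), dims[[1]])) {
      return("label shape must match the volumes")
    }
  }
  TRUE
})

#' Construct a MultimodalCase
#' @param caseId subject identifier.
#' @param volumes named list of \linkS4class{BrainVolume}s.
#' @param label optional \linkS4class{LabelVolume}.
#' @return a \linkS4class{MultimodalCase}.
#' @export
MultimodalCase <- function(caseId, volumes, label = NULL) {
  new("MultimodalCase", caseId = caseId, volumes = volumes, label = label)
}

#' Overlapping binary target regions: whole tumor, tumor core, enhancing
#'
#' The three masks are nested: et is contained in tc, tc in wt.
#' @slot wt,tc,et binary (0/1) 3D arrays of one shape.
#' @export
setClass("RegionMasks",
  representation(wt = "array", tc = "array", et = "array"))

setValidity("RegionMasks", function(object) {
  d <- dim(object@wt)
  if (!identical(dim(object@tc), d) || !identical(dim(object@et), d)) {
    return("wt, tc and et must share a shape")
  }
  for (nm in REGION_NAMES) {
    v <- slot(object, nm)
    if (!all(v %in% c(0, 1))) return(sprintf("%s must be binary", nm))
  }
  if (any(object@et > object@tc)) return("et must be contained in tc")
  if (any(object@tc > object@wt)) return("tc must be contained in wt")
  TRUE
})

#' Construct RegionMasks
#' @param wt,tc,et binary 3D arrays with et <= tc <= wt voxelwise.
#' @return a \linkS4class{RegionMasks}.
#' @export
RegionMasks <- function(wt, tc, et) {
  new("RegionMasks", wt = wt, tc = tc, et = et)
}

#' A half-open axis-aligned window \[origin, origin + size) in voxel space
#'
#' Origins are 0-based to match the sliding-window convention.
#' @slot origin integer triple, 0-based voxel index.
#' @slot size integer triple of window extents.
#' @export
setClass("WindowSpec",
  representation(origin = "integer", size = "integer"))

setValidity("WindowSpec", function(object) {
  if (length(object@origin) != 3L || length(object@size) != 3L) {
    return("origin and size must be integer triples")
  }
  if (any(object@origin < 0L)) return("origin must be non-negative")
  if (any(object@size < 1L)) return("size must be positive")
  TRUE
})

#' Construct a WindowSpec
#' @param origin 0-based integer voxel triple.
#' @param size integer extent triple.
#' @return a \linkS4class{WindowSpec}.
#' @export
WindowSpec <- function(origin, size) {
  new("WindowSpec", origin = as.integer(origin), size = as.integer(size))
}

#' Synthetic multimodal phantom specification
#'
#' Defines the study conditions the generator emulates: a skull-stripped
#' ellipsoidal brain with exactly-zero background, nested tumor
#' sub-regions with irregular boundaries, modality-specific tissue
#' contrast and additive Gaussian noise.
#'
#' @slot shape volume extents (each at least 16 voxels).
#' @slot nCases number of cases in a generated dataset.
#' @slot seed base RNG seed; per-case seeds are derived from it.
#' @slot noiseSigma standard deviation of additive noise, in the same
#'   arbitrary intensity units as the contrast table.
#' @slot contrastTable modality x tissue mean-intensity matrix with rows
#'   t1, t1c, t2, flair and columns brain, ed, ncr, et.
#' @slot tumorRadiusRange whole-tumor radius range as a fraction of the
#'   smallest brain semi-axis.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", nCases = "integer", seed = "integer",
                 noiseSigma = "numeric", contrastTable = "matrix",
                 tumorRadiusRange = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 16L)) {
    return("shape must be an integer triple with every extent >= 16")
  }
  if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
  if (object@nCases < 1L) return("nCases must be positive")
  ct <- object@contrastTable
  if (!all(rownames(ct) == SOURCE_MODALITIES) ||
      !all(colnames(ct) == c("brain", "ed", "ncr", "et"))) {
    return("contrastTable must have rows t1,t1c,t2,flair and columns brain,ed,ncr,et")
  }
  if (any(ct <= 0)) return("contrast means must be positive")
  rr <- object@tumorRadiusRange
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] >= 1 || rr[1] > rr[2]) {
    return("tumorRadiusRange must be an increasing pair inside (0, 1)")
  }
  TRUE
})

#' Fusion loss configuration
#'
#' Holds the trade-off scalars of the composite fusion loss
#' L = L_pixel + alpha * L_ssim with
#' L_pixel = ||F - S1||^2 + beta * ||F - S2||^2 and
#' L_ssim = gamma * (1 - SSIM(F, S1)) + (1 - SSIM(F, S2)).
#'
#' @slot alpha weight of the structural-similarity term (default 450).
#' @slot beta pixel-loss weight on the second source.
#' @slot gamma SSIM weight on the first source.
#' @slot ssimWindow odd cubic window side for the 3D SSIM.
#' @slot k1,k2 SSIM stabilizers.
#' @export
setClass("FusionLossConfig",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 ssimWindow = "integer", k1 = "numeric", k2 = "numeric"))

setValidity("FusionLossConfig", function(object) {
  if (object@alpha <= 0 || object@beta <= 0 || object@gamma <= 0) {
    return("alpha, beta and gamma must be positive")
  }
  if (object@ssimWindow < 3L || object@ssimWindow %% 2L == 0L) {
    return("ssimWindow must be odd and at least 3")
  }
  TRUE
})

#' Construct a FusionLossConfig
#'
#' Defaults follow the pairing convention: for the T2+Flair fusion both
#' sources carry equal weight (beta = gamma = 1); for the T1c-led
#' pairings the second source gets a doubled pixel weight and the T1c
#' source a doubled structural weight (beta = gamma = 2).
#'
#' @param pairing one of "t2+flair", "t1c+t2", "t1c+flair"; sets the
#'   beta/gamma defaults.
#' @param alpha SSIM regularization weight.
#' @param beta,gamma override the pairing defaults.
#' @param ssimWindow,k1,k2 SSIM parameters.
#' @return a \linkS4class{FusionLossConfig}.
#' @export
fusionLossConfig <- function(pairing = "t2+flair", alpha = 450,
                             beta = NULL, gamma = NULL,
                             ssimWindow = 7L, k1 = 0.01, k2 = 0.03) {
  pairing <- match.arg(pairing, c("t2+flair", "t1c+t2", "t1c+flair"))
  def <- if (pairing == "t2+flair") 1 else 2
  new("FusionLossConfig", alpha = alpha,
      beta = if (is.null(beta)) def else beta,
      gamma = if (is.null(gamma)) def else gamma,
      ssimWindow = as.integer(ssimWindow), k1 = k1, k2 = k2)
}

#' Segmentation loss configuration
#'
#' @slot lambda weight of the binary cross-entropy term next to the Dice
#'   term (default 0.5).
#' @slot epsilon small constant protecting the Dice denominator.
#' @export
setClass("SegLossConfig",
  representation(lambda = "numeric", epsilon = "numeric"))

setValidity("SegLossConfig", function(object) {
  if (object@lambda < 0) return("lambda must be non-negative")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' Construct a SegLossConfig
#' @param lambda BCE weight (default 0.5).
#' @param epsilon Dice smoothing constant (default 1e-5).
#' @return a \linkS4class{SegLossConfig}.
#' @export
segLossConfig <- function(lambda = 0.5, epsilon = 1e-5) {
  new("SegLossConfig", lambda = lambda, epsilon = epsilon)
}

#' Modality-selection feature-fusion configuration
#'
#' @slot nModalities number of input branches N.
#' @slot channels feature channels C per branch (default 16).
#' @slot reduction channel-reduction ratio r of the bottleneck (default 4).
#' @export
setClass("MsffConfig",
  representation(nModalities = "integer", channels = "integer",
                 reduction = "integer"))

setValidity("MsffConfig", function(object) {
  if (object@nModalities < 1L) return("need at least one modality")
  if (object@channels %% object@reduction != 0L) {
    return("channels must be divisible by the reduction ratio")
  }
  TRUE
})

#' Construct an MsffConfig
#' @param nModalities number of input modality branches.
#' @param channels per-branch feature channels (default 16).
#' @param reduction bottleneck reduction ratio (default 4).
#' @return an \linkS4class{MsffConfig}.
#' @export
msffConfig <- function(nModalities, channels = 16L, reduction = 4L) {
  new("MsffConfig", nModalities = as.integer(nModalities),
      channels = as.integer(channels), reduction = as.integer(reduction))
}

#' Configuration of one segmentation stage
#'
#' Stage 1 segments the whole tumor from T2, Flair and their fused
#' modality; stage 2 segments tumor core and enhancing tumor from all
#' four sources plus the two T1c-led fused modalities, inside the window
#' located by stage 1.
#'
#' @slot stage 1 or 2.
#' @slot inputModalities ordered modality names fed to the attention
#'   front-end.
#' @slot outputRegions region names predicted by the stage head.
#' @slot cropSize training crop extents.
#' @slot depth number of V-Net resolution levels.
#' @slot channels feature width entering the backbone (equals the
#'   attention module's channel count).
#' @export
setClass("StageConfig",
  representation(stage = "integer", inputModalities = "character",
                 outputRegions = "character", cropSize = "integer",
                 depth = "integer", channels = "integer"))

setValidity("StageConfig", function(object) {
  if (!object@stage %in% c(1L, 2L)) return("stage must be 1 or 2")
  if (length(object@cropSize) != 3L) return("cropSize must be a triple")
  if (object@depth < 1L) return("depth must be at least 1")
  if (any(object@cropSize %% 2L^(object@depth - 1L) != 0L)) {
    return("cropSize must be divisible by 2^(depth - 1)")
  }
  if (!all(object@outputRegions %in% REGION_NAMES)) {
    return("outputRegions must be among wt, tc, et")
  }
  TRUE
})

#' Construct a StageConfig
#'
#' Full-scale defaults follow the training protocol: stage-1 crops of
#' 128 x 192 x 160 over {t2, flair, t2-flair}, stage-2 crops of 128^3
#' over all six modalities, V-Net depth 4.  For desk-scale phantoms pass
#' small crops and a reduced depth.
#'
#' @param stage 1 or 2.
#' @param cropSize training crop extents (defaults per stage).
#' @param depth V-Net resolution levels (default 4).
#' @param channels backbone input feature width (default 16).
#' @return a \linkS4class{StageConfig}.
#' @export
stageConfig <- function(stage, cropSize = NULL, depth = 4L, channels = 16L) {
  stage <- as.integer(stage)
  if (is.null(cropSize)) {
    cropSize <- if (stage == 1L) c(128L, 192L, 160L) else c(128L, 128L, 128L)
  }
  mods <- if (stage == 1L) {
    c("t2", "flair", "t2-flair")
  } else {
    c("t1", "t1c", "t2", "flair", "t1c-t2", "t1c-flair")
  }
  regions <- if (stage == 1L) "wt" else c("tc", "et")
  new("StageConfig", stage = stage, inputModalities = mods,
      outputRegions = regions, cropSize = as.integer(cropSize),
      depth = as.integer(depth), channels = as.integer(channels))
}

#' A trained pixel-level fusion network
#'
#' Two-branch 3D residual network predicting a sigmoid weight mask; the
#' fused volume is the voxelwise convex combination
#' F = M * S1 + (1 - M) * S2.
#'
#' @slot pairing the modality pairing the network was trained for.
#' @slot channels feature width of the branch convolutions.
#' @slot params nested list of trainable parameter nodes.
#' @slot lossConfig the \linkS4class{FusionLossConfig} used in training.
#' @slot history numeric vector of per-step training losses.
#' @export
setClass("PifNet",
  representation(pairing = "character", channels = "integer",
                 params = "list", lossConfig = "ANY", history = "numeric"))

#' A trained segmentation stage (attention front-end + V-Net)
#'
#' @slot config the \linkS4class{StageConfig}.
#' @slot msff the \linkS4class{MsffConfig} of the front-end.
#' @slot params nested list of trainable parameter nodes.
#' @slot history per-epoch mean training losses.
#' @export
setClass("StageModel",
  representation(config = "StageConfig", msff = "MsffConfig",
                 params = "list", history = "numeric"))
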