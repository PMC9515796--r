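# Segmentation backbone: attention front-end + V-Net style encoder-decoder.
#
# The fused 16-channel feature block from the modality-selection module
# enters a symmetric encoder-decoder.  Each resolution level holds a
# residual block of two 3x3x3 convolutions with instance normalization;
# downsampling is a 2x2x2 stride-2 convolution doubling the channels,
# upsampling is nearest-neighbour followed by a 3x3x3 convolution halving
# them, with encoder features concatenated back in.  One 1x1x1 sigmoid
# head per output region.

vnetChannels <- function(cfg) cfg@channels * 2L^(seq_len(cfg@depth) - 1L)

#' Build an untrained segmentation stage
#'
#' @param cfg a \linkS4class{StageConfig}.
#' @param msffCfg attention front-end configuration; defaults to the
#'   stage's modality count with the backbone's channel width.
#' @param seed RNG seed for weight initialization.
#' @return an untrained \linkS4class{StageModel}.
#' @export
buildStageNet <- function(cfg, msffCfg = NULL, seed = 1L) {
  stopifnot(is(cfg, "StageConfig"))
  if (is.null(msffCfg)) {
    msffCfg <- msffConfig(length(cfg@inputModalities), channels = cfg@channels)
  }
  if (msffCfg@nModalities != length(cfg@inputModalities)) {
    stop("attention module branch count must match the stage's modalities")
  }
  if (msffCfg@channels != cfg@channels) {
    stop("attention channel width must match the backbone input width")
  }
  ch <- vnetChannels(cfg)
  L <- cfg@depth
  params <- withSeed(seed, function() {
    blockInit <- function(c) list(c1 = convInit(3L, c, c), c2 = convInit(3L, c, c))
    p <- list(msff = msffInit(msffCfg, seed = seed + 1L),
              enc = lapply(ch, blockInit))
    if (L > 1L) {
      p$down <- lapply(seq_len(L - 1L), function(l)
        convInit(2L, ch[l], ch[l + 1L]))
      p$up <- lapply(seq_len(L - 1L), function(l)
        convInit(3L, ch[l + 1L], ch[l]))
      p$merge <- lapply(seq_len(L - 1L), function(l)
        convInit(3L, 2L * ch[l], ch[l]))
      p$dec <- lapply(seq_len(L - 1L), function(l) blockInit(ch[l]))
    }
    p$head <- lapply(cfg@outputRegions, function(r) convInit(1L, ch[1], 1L))
    names(p$head) <- cfg@outputRegions
    p
  })
  new("StageModel", config = cfg, msff = msffCfg, params = params,
      history = numeric(0))
}

# residual block with instance normalization
agVnetBlock <- function(x, p) {
  h <- agRelu(agInstanceNorm(agConv3d(x, p$c1$w, p$c1$b)))
  h <- agInstanceNorm(agConv3d(h, p$c2$w, p$c2$b))
  agRelu(agAdd(h, x))
}

# full forward pass; inputs is a list of 3D arrays (one per modality)
stageForwardNode <- function(model, inputs) {
  cfg <- model@config
  p <- model@params
  L <- cfg@depth
  d <- dim(inputs[[1]])
  if (any(d %% 2L^(L - 1L) != 0L)) {
    stop("input extents must be divisible by 2^(depth - 1)")
  }
  ms <- msffForwardNode(inputs, p$msff, model@msff)
  x <- ms$fused
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    x <- agVnetBlock(x, p$enc[[l]])
    skips[[l]] <- x
    if (l < L) x <- agRelu(agConv3d(x, p$down[[l]]$w, p$down[[l]]$b,
                                    stride = 2L, pad = 0L))
  }
  if (L > 1L) {
    for (l in rev(seq_len(L - 1L))) {
      x <- agRelu(agConv3d(agUpsample2(x), p$up[[l]]$w, p$up[[l]]$b))
      x <- agRelu(agConv3d(agConcatC(x, skips[[l]]), p$merge[[l]]$w,
                           p$merge[[l]]$b))
      x <- agVnetBlock(x, p$dec[[l]])
    }
  }
  probs <- lapply(cfg@outputRegions, function(r)
    agSigmoid(agConv3d(x, p$head[[r]]$w, p$head[[r]]$b, pad = 0L)))
  names(probs) <- cfg@outputRegions
  list(probs = probs, attention = ms$attention)
}

#' Forward pass of a segmentation stage
#'
#' @param model a \linkS4class{StageModel}.
#' @param inputs list of numeric 3D arrays, one per input modality, in
#'   the order of the stage configuration.
#' @return named list of per-region probability arrays with the input
#'   shape, values in \[0, 1\].
#' @export
stageForward <- function(model, inputs) {
  out <- stageForwardNode(model, inputs)
  lapply(out$probs, function(p) {
    v <- p$value
    dim(v) <- dim(v)[1:3]
    v
  })
}
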