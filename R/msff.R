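# Modality-selection feature fusion.
#
# Each of the N input volumes passes through its own 3x3x3 convolution
# (C = 16 channels); the feature blocks are merged by element-wise
# summation, pooled to a channel vector by global average pooling,
# compressed by a 1x1x1 bottleneck (ratio r = 4, ReLU), expanded by N
# parallel 1x1x1 excitation maps, and normalized by a softmax across
# branches separately for each channel.  The fused feature block is the
# attention-weighted sum of the branch features — a per-channel convex
# combination, so every fused element stays inside the envelope of the
# branch features.

#' Initialize parameters of the modality-selection module
#'
#' @param cfg an \linkS4class{MsffConfig}.
#' @param seed RNG seed.
#' @return nested parameter list (per-modality extractors, bottleneck,
#'   per-branch excitations).
#' @export
msffInit <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "MsffConfig"))
  withSeed(seed, function() {
    list(
      extract = lapply(seq_len(cfg@nModalities), function(i)
        convInit(3L, 1L, cfg@channels)),
      reduce = denseInit(cfg@channels, cfg@channels %/% cfg@reduction),
      excite = lapply(seq_len(cfg@nModalities), function(i)
        denseInit(cfg@channels %/% cfg@reduction, cfg@channels)))
  })
}

# autograd path used inside the segmentation network; inputs are nodes
# with value dim (D,H,W,1) or plain arrays
msffForwardNode <- function(inputs, params, cfg) {
  n <- cfg@nModalities
  if (length(inputs) != n) {
    stop(sprintf("expected %d input modalities, got %d", n, length(inputs)))
  }
  u <- vector("list", n)
  for (i in seq_len(n)) {
    x <- inputs[[i]]
    if (!inherits(x, "agNode")) {
      if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
      x <- agConst(x)
    }
    u[[i]] <- agRelu(agConv3d(x, params$extract[[i]]$w, params$extract[[i]]$b))
  }
  um <- u[[1]]
  if (n > 1L) for (i in 2:n) um <- agAdd(um, u[[i]])
  s <- agGap(um)
  z <- agRelu(agDense(s, params$reduce$w, params$reduce$b))
  t <- lapply(seq_len(n), function(i)
    agDense(z, params$excite[[i]]$w, params$excite[[i]]$b))
  att <- agBranchSoftmax(t)
  v <- NULL
  for (i in seq_len(n)) {
    term <- agScaleChannels(u[[i]], agRow(att, i))
    v <- if (is.null(v)) term else agAdd(v, term)
  }
  list(fused = v, features = u, attention = att)
}

#' Per-modality feature extraction
#'
#' Applies each modality's independent 3x3x3 convolution (stride 1,
#' padding 1, ReLU) to its input volume.
#'
#' @param volumes list of N numeric 3D arrays of one shape.
#' @param params parameters from \code{\link{msffInit}}.
#' @param cfg the \linkS4class{MsffConfig}.
#' @return list of N feature arrays, each (D, H, W, C).
#' @export
extractFeatures <- function(volumes, params, cfg) {
  n <- cfg@nModalities
  if (length(volumes) != n) {
    stop(sprintf("expected %d input modalities, got %d", n, length(volumes)))
  }
  lapply(seq_len(n), function(i) {
    x <- volumes[[i]]
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    y <- cpp_conv3d_fw(x, dim(x), params$extract[[i]]$w$value,
                       dim(params$extract[[i]]$w$value),
                       params$extract[[i]]$b$value, 1L, 1L)
    y * (y > 0)
  })
}

#' Element-wise sum of the branch feature blocks
#' @param features list of same-shaped feature arrays.
#' @return their element-wise sum.
#' @export
mergeSum <- function(features) {
  Reduce(`+`, features)
}

#' Channel-wise global average pooling
#' @param u feature array (D, H, W, C).
#' @return channel vector of length C.
#' @export
globalPool <- function(u) {
  d <- dim(u)
  colMeans(matrix(u, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Branch attention weights from a pooled channel vector
#'
#' Bottleneck (1x1x1 reduction, ReLU), N parallel excitations, then a
#' softmax across branches for every channel: the returned N x C matrix
#' has columns summing to 1 with all entries in (0, 1).
#'
#' @param s pooled channel vector (length C).
#' @param params parameters from \code{\link{msffInit}}.
#' @param cfg the \linkS4class{MsffConfig}.
#' @return N x C matrix of attention weights.
#' @export
attentionWeights <- function(s, params, cfg) {
  z <- pmax(drop(s %*% params$reduce$w$value) + params$reduce$b$value, 0)
  tm <- do.call(rbind, lapply(seq_len(cfg@nModalities), function(i)
    drop(z %*% params$excite[[i]]$w$value) + params$excite[[i]]$b$value))
  tm <- sweep(tm, 2, apply(tm, 2, max))
  e <- exp(tm)
  sweep(e, 2, colSums(e), "/")
}

#' Attention-weighted recombination of branch features
#'
#' @param features list of N feature arrays (D, H, W, C).
#' @param att N x C attention matrix with columns summing to 1.
#' @return fused feature array (D, H, W, C), element-wise within the
#'   envelope of the branch features.
#' @export
fuseFeatures <- function(features, att) {
  d <- dim(features[[1]])
  v <- array(0, dim = d)
  for (i in seq_along(features)) {
    vm <- sweep(matrix(features[[i]], nrow = prod(d[1:3])), 2, att[i, ], "*")
    v <- v + array(vm, dim = d)
  }
  v
}

#' Full forward pass of the modality-selection module
#'
#' Composition of feature extraction, merge, pooling, attention and
#' recombination.
#'
#' @param volumes list of N numeric 3D arrays.
#' @param params parameters from \code{\link{msffInit}}.
#' @param cfg the \linkS4class{MsffConfig}.
#' @return list with the fused feature block \code{fused} (D, H, W, C)
#'   and the \code{attention} matrix (N x C).
#' @export
msffForward <- function(volumes, params, cfg) {
  u <- extractFeatures(volumes, params, cfg)
  s <- globalPool(mergeSum(u))
  att <- attentionWeights(s, params, cfg)
  list(fused = fuseFeatures(u, att), attention = att, features = u)
}
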