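# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for the core data classes
#' @param x object.
#' @param ... further arguments for methods.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname accessors
#' @export
setMethod("volAffine", "BrainVolume", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname accessors
#' @export
setMethod("caseId", "MultimodalCase", function(x) x@caseId)

#' @rdname accessors
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))

#' @rdname accessors
#' @export
setMethod("modalities", "MultimodalCase", function(x) names(x@volumes))

#' @rdname accessors
#' @param modality modality name such as "t2" or "t2-flair".
#' @export
setGeneric("getVolume", function(x, modality) standardGeneric("getVolume"))

#' @rdname accessors
#' @export
setMethod("getVolume", "MultimodalCase", function(x, modality) {
  if (!modality %in% names(x@volumes)) {
    stop(sprintf("case '%s' has no modality '%s'", x@caseId, modality))
  }
  x@volumes[[modality]]
})

#' @rdname accessors
#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))

#' @rdname accessors
#' @export
setMethod("caseLabel", "MultimodalCase", function(x) x@label)

#' @rdname accessors
#' @param region one of "wt", "tc", "et".
#' @export
setGeneric("regionMask", function(x, region) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setMethod("regionMask", "RegionMasks", function(x, region) {
  slot(x, match.arg(region, REGION_NAMES))
})

#' @rdname accessors
#' @export
setGeneric("windowOrigin", function(x) standardGeneric("windowOrigin"))

#' @rdname accessors
#' @export
setMethod("windowOrigin", "WindowSpec", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname accessors
#' @export
setMethod("windowSize", "WindowSpec", function(x) x@size)

#' Total number of trainable parameters of a model
#' @param x a \linkS4class{PifNet} or \linkS4class{StageModel}.
#' @return integer parameter count.
#' @export
setGeneric("paramCount", function(x) standardGeneric("paramCount"))

countParams <- function(params) {
  sum(vapply(agParamList(params), function(p) length(p$value), numeric(1)))
}

#' @rdname paramCount
#' @export
setMethod("paramCount", "PifNet", function(x) countParams(x@params))

#' @rdname paramCount
#' @export
setMethod("paramCount", "StageModel", function(x) countParams(x@params))

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("BrainVolume %s, range [%.3g, %.3g]\n",
              paste(dim(object@data), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "MultimodalCase", function(object) {
  cat(sprintf("MultimodalCase '%s': %s, modalities: %s, label: %s\n",
              object@caseId,
              paste(dim(object@volumes[[1]]@data), collapse = " x "),
              paste(names(object@volumes), collapse = ", "),
              if (is.null(object@label)) "none" else "present"))
})

setMethod("show", "RegionMasks", function(object) {
  cat(sprintf("RegionMasks %s: |wt|=%d |tc|=%d |et|=%d\n",
              paste(dim(object@wt), collapse = " x "),
              sum(object@wt), sum(object@tc), sum(object@et)))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec origin (%s), size (%s)\n",
              paste(object@origin, collapse = ", "),
              paste(object@size, collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s, %d case(s), seed %d, noise sd %.3g\n",
              paste(object@shape, collapse = " x "), object@nCases,
              object@seed, object@noiseSigma))
})

setMethod("show", "PifNet", function(object) {
  cat(sprintf(
    "PifNet pairing '%s', %d channels, %d parameters, %d training steps\n",
    object@pairing, object@channels, paramCount(object),
    length(object@history)))
})

setMethod("show", "StageModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "StageModel stage %d: %d modalities -> regions %s, depth %d, %d parameters\n",
    cfg@stage, length(cfg@inputModalities),
    paste(cfg@outputRegions, collapse = "/"), cfg@depth,
    paramCount(object)))
})
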