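# Case IO in the BraTS directory layout, intensity normalization,
# label/region conversions and tumor-window extraction.
#
# Axis convention throughout: (depth, height, width), 0-based window
# origins, half-open windows [origin, origin + size).

#' Z-score normalization over the non-zero support
#'
#' Subtracts the mean and divides by the (population) standard deviation
#' of the non-zero region only; voxels that are exactly zero — the
#' skull-stripped background — remain exactly zero.  The result is
#' invariant to positive affine rescaling of the non-zero region.
#'
#' @param v a \linkS4class{BrainVolume}.
#' @return a \linkS4class{BrainVolume} with standardized intensities.
#' @examples
#' v <- BrainVolume(array(c(0, 2, 4, 0), dim = c(4, 1, 1)))
#' volData(zscoreNormalize(v))  # 0, -1, 1, 0
#' @export
zscoreNormalize <- function(v) {
  stopifnot(is(v, "BrainVolume"))
  x <- v@data
  support <- x != 0
  n <- sum(support)
  if (n == 0L) stop("degenerate input: all-zero volume")
  vals <- x[support]
  mu <- mean(vals)
  sdv <- sqrt(mean((vals - mu)^2))
  if (sdv == 0) stop("degenerate input: zero standard deviation on the non-zero support")
  x[support] <- (vals - mu) / sdv
  BrainVolume(x, v@affine)
}

#' Convert a BraTS label volume to overlapping region masks
#'
#' Whole tumor is the union of all tumor labels, tumor core excludes
#' edema, enhancing tumor is label 4 alone.  The outputs are nested:
#' et <= tc <= wt.
#'
#' @param l a \linkS4class{LabelVolume}.
#' @return a \linkS4class{RegionMasks}.
#' @export
labelsToRegions <- function(l) {
  stopifnot(is(l, "LabelVolume"))
  x <- l@data
  wt <- array(as.numeric(x %in% c(1, 2, 4)), dim = dim(x))
  tc <- array(as.numeric(x %in% c(1, 4)), dim = dim(x))
  et <- array(as.numeric(x == 4), dim = dim(x))
  RegionMasks(wt = wt, tc = tc, et = et)
}

#' Assemble a BraTS label volume from nested region masks
#'
#' Inverse of \code{\link{labelsToRegions}}: enhancing tumor voxels get
#' label 4, the rest of the core label 1, the rest of the whole tumor
#' label 2 (edema), everything else 0.
#'
#' @param r a \linkS4class{RegionMasks} (nesting is enforced by the class).
#' @param affine optional 4x4 transform for the output volume.
#' @return a \linkS4class{LabelVolume}.
#' @export
regionsToLabels <- function(r, affine = diag(4)) {
  stopifnot(is(r, "RegionMasks"))
  x <- array(0L, dim = dim(r@wt))
  x[r@wt == 1] <- 2L
  x[r@tc == 1] <- 1L
  x[r@et == 1] <- 4L
  LabelVolume(x, affine)
}

#' Locate the window containing the most tumor voxels
#'
#' Scans candidate origins on a stride grid (the final in-bounds origin
#' along each axis is always included) and returns the half-open window
#' with the maximal mask sum.  Ties are broken by the first origin in
#' lexicographic (depth, height, width) order.
#'
#' @param mask binary 3D array.
#' @param size integer window extents.
#' @param stride origin grid step in voxels (1 = exhaustive scan).
#' @return a \linkS4class{WindowSpec}.
#' @export
maxTumorWindow <- function(mask, size, stride = 1L) {
  d <- dim(mask)
  size <- as.integer(size)
  if (length(size) != 3L) stop("size must be an integer triple")
  if (any(size > d)) stop("window size exceeds the volume shape")
  # integral image with a leading zero plane per axis
  p <- array(0, dim = d + 1L)
  p[-1, -1, -1] <- mask
  p <- apply(p, c(2, 3), cumsum)                 # cumulate along depth
  p <- aperm(apply(p, c(1, 3), cumsum), c(2, 1, 3))  # ... height
  p <- aperm(apply(p, c(1, 2), cumsum), c(2, 3, 1))  # ... width
  orig <- lapply(1:3, function(a) {
    g <- unique(c(seq(0L, d[a] - size[a], by = as.integer(stride)),
                  d[a] - size[a]))
    sort(g)
  })
  winSum <- function(o1, o2, o3) {
    a <- o1 + 1L; b <- o2 + 1L; c2 <- o3 + 1L
    A <- a + size[1]; B <- b + size[2]; C <- c2 + size[3]
    p[A, B, C] - p[a, B, C] - p[A, b, C] - p[A, B, c2] +
      p[a, b, C] + p[a, B, c2] + p[A, b, c2] - p[a, b, c2]
  }
  sums <- array(0, dim = lengths(orig))
  for (k in seq_along(orig[[3]]))
    for (j in seq_along(orig[[2]]))
      sums[, j, k] <- vapply(orig[[1]], winSum, numeric(1),
                             o2 = orig[[2]][j], o3 = orig[[3]][k])
  ties <- which(sums == max(sums), arr.ind = TRUE)
  o <- c(orig[[1]][ties[, 1]], orig[[2]][ties[, 2]], orig[[3]][ties[, 3]])
  o <- matrix(o, ncol = 3)
  o <- o[order(o[, 1], o[, 2], o[, 3]), , drop = FALSE][1, ]
  WindowSpec(origin = o, size = size)
}

#' Crop an array to a window
#' @param x 3D array.
#' @param ws a \linkS4class{WindowSpec}.
#' @return the cropped array.
#' @export
cropWindow <- function(x, ws) {
  o <- ws@origin; s <- ws@size
  if (any(o + s > dim(x))) stop("window exceeds the volume")
  x[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]), o[3] + seq_len(s[3]),
    drop = FALSE]
}

#' Zero-pad an array symmetrically to a target shape
#' @param x 3D array.
#' @param shape target extents (each >= the current extent).
#' @return list with the padded array and the 0-based offset of the
#'   original data inside it.
#' @export
padToShape <- function(x, shape) {
  d <- dim(x)
  shape <- as.integer(shape)
  if (any(shape < d)) stop("target shape smaller than the volume")
  off <- (shape - d) %/% 2L
  out <- array(0, dim = shape)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- x
  list(data = out, offset = off)
}

caseFile <- function(dir, id, modality) {
  file.path(dir, sprintf("%s_%s.nii.gz", id, modality))
}

#' Write a case to a BraTS-style directory
#'
#' Creates \code{<dir>/<caseId>/} containing one NIfTI file per modality
#' (\code{<caseId>_<modality>.nii.gz}) and \code{<caseId>_seg.nii.gz}
#' when a label is present.  Affines are preserved.
#'
#' @param case a \linkS4class{MultimodalCase}.
#' @param dir parent directory.
#' @return the case directory path, invisibly.
#' @export
writeCase <- function(case, dir) {
  stopifnot(is(case, "MultimodalCase"))
  cdir <- file.path(dir, case@caseId)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  writeVol <- function(vol, path) {
    img <- RNifti::asNifti(vol@data)
    img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
    RNifti::writeNifti(img, path)
  }
  for (m in names(case@volumes)) {
    writeVol(case@volumes[[m]], caseFile(cdir, case@caseId, m))
  }
  if (!is.null(case@label)) {
    writeVol(case@label, caseFile(cdir, case@caseId, "seg"))
  }
  invisible(cdir)
}

#' Read a case from a BraTS-style directory
#'
#' @param path the case directory; its basename is the case id.
#' @param modalities modality files to require (default the four
#'   sources); fused modalities present on disk are picked up
#'   automatically.
#' @param label if TRUE, require \code{<id>_seg.nii.gz}; if NA (default)
#'   read it when present.
#' @return a \linkS4class{MultimodalCase}.
#' @export
readCase <- function(path, modalities = SOURCE_MODALITIES, label = NA) {
  id <- basename(path)
  readVol <- function(f) {
    img <- RNifti::readNifti(f)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    BrainVolume(arr, structure(unclass(RNifti::xform(img)),
                               imagedim = NULL, code = NULL))
  }
  vols <- list()
  for (m in modalities) {
    f <- caseFile(path, id, m)
    if (!file.exists(f)) stop(sprintf("case '%s': missing modality '%s' (%s)",
                                      id, m, f))
    vols[[m]] <- readVol(f)
  }
  for (m in setdiff(FUSED_MODALITIES, modalities)) {
    f <- caseFile(path, id, m)
    if (file.exists(f)) vols[[m]] <- readVol(f)
  }
  segf <- caseFile(path, id, "seg")
  lab <- NULL
  if (isTRUE(label) && !file.exists(segf)) {
    stop(sprintf("case '%s': missing label volume", id))
  }
  if (file.exists(segf) && !isFALSE(label)) {
    lv <- readVol(segf)
    lab <- LabelVolume(array(as.integer(round(lv@data)), dim = dim(lv@data)),
                       lv@affine)
  }
  MultimodalCase(caseId = id, volumes = vols, label = lab)
}
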