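# Evaluation metrics: Dice overlap and 95th-percentile Hausdorff
# surface distance, with explicit empty-set conventions.

#' Dice overlap score between two binary masks
#'
#' \code{2|A∩B| / (|A| + |B|)}; two empty masks score 1 by convention.
#'
#' @param a,b binary 3D arrays (or logical) of one shape.
#' @return scalar in \[0, 1\].
#' @export
diceScore <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share a shape")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum((a != 0) & (b != 0)) / (sa + sb)
}

#' 95th-percentile symmetric Hausdorff surface distance
#'
#' Surface voxels are mask voxels with at least one six-connected
#' background neighbour (the array border counts as background).  The
#' directed distances from each surface of one mask to the nearest
#' surface voxel of the other are reduced to their 95th percentile
#' (linear interpolation on the sorted distances), and the larger of the
#' two directions is returned.  Both masks empty gives 0; exactly one
#' empty gives the sentinel.
#'
#' @param a,b binary 3D arrays of one shape.
#' @param spacing voxel spacing along (depth, height, width).
#' @param prob percentile as a fraction (default 0.95).
#' @param sentinel value returned when exactly one mask is empty
#'   (default 373.1287, the diagonal of a 240-cube grid).
#' @return scalar distance in spacing units.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), prob = 0.95,
                 sentinel = 373.1287) {
  if (!all(dim(a) == dim(b))) stop("masks must share a shape")
  ea <- sum(a != 0) == 0
  eb <- sum(b != 0) == 0
  if (ea && eb) return(0)
  if (ea || eb) return(sentinel)
  dd <- cpp_surface_dists(array(as.integer(a != 0), dim = dim(a)),
                          array(as.integer(b != 0), dim = dim(b)),
                          dim(a), as.numeric(spacing))
  max(stats::quantile(dd$ab, prob, names = FALSE),
      stats::quantile(dd$ba, prob, names = FALSE))
}

#' Evaluate predictions against references, per case and per region
#'
#' Converts both label volumes to the overlapping regions and scores
#' Dice and HD95 for each; a final row per region holds the arithmetic
#' mean over cases.
#'
#' @param preds named list of predicted \linkS4class{LabelVolume}s.
#' @param refs named list of reference \linkS4class{LabelVolume}s with
#'   matching names.
#' @param spacing voxel spacing passed to \code{\link{hd95}}.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns case_id, region, dice, hd95.
#' @export
evaluateDataset <- function(preds, refs, spacing = c(1, 1, 1), file = NULL) {
  if (!all(names(preds) %in% names(refs))) {
    stop("every prediction needs a matching reference")
  }
  rows <- list()
  for (id in names(preds)) {
    rp <- labelsToRegions(preds[[id]])
    rr <- labelsToRegions(refs[[id]])
    for (region in REGION_NAMES) {
      a <- regionMask(rp, region)
      b <- regionMask(rr, region)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = id, region = region,
        dice = diceScore(a, b), hd95 = hd95(a, b, spacing))
    }
  }
  tab <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(REGION_NAMES, function(region) {
    sub <- tab[tab$region == region, ]
    data.frame(case_id = "mean", region = region,
               dice = mean(sub$dice), hd95 = mean(sub$hd95))
  }))
  out <- rbind(tab, means)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
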