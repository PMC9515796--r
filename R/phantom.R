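# Synthetic multimodal phantom generator.
#
# Each case is an ellipsoidal "brain" with exactly-zero background
# (emulating skull-stripped data), a nested tumor (enhancing core inside
# tumor core inside whole tumor) with irregular perturbed-ellipsoid
# boundaries, modality-specific tissue contrast (edema bright in T2 and
# Flair, enhancing core bright in T1c, necrosis dark in T1c) and additive
# Gaussian noise inside the brain support.

defaultContrastTable <- function() {
  ct <- rbind(
    t1    = c(brain = 1.00, ed = 0.70, ncr = 0.55, et = 0.90),
    t1c   = c(brain = 1.00, ed = 0.80, ncr = 0.35, et = 1.80),
    t2    = c(brain = 0.80, ed = 1.60, ncr = 1.10, et = 1.20),
    flair = c(brain = 0.90, ed = 1.70, ncr = 1.00, et = 1.10))
  ct
}

#' Construct a PhantomSpec
#'
#' @param shape volume extents, each at least 16 (default 32^3).
#' @param nCases number of cases for \code{\link{makePhantomDataset}}.
#' @param seed base RNG seed.
#' @param noiseSigma additive Gaussian noise standard deviation inside
#'   the brain, in the intensity units of the contrast table
#'   (default 0.05, i.e. roughly 5\% of healthy-tissue intensity).
#' @param contrastTable modality x tissue mean-intensity matrix; the
#'   default encodes the standard clinical contrast pattern.
#' @param tumorRadiusRange whole-tumor radius as a fraction of the
#'   smallest brain semi-axis (default 0.35 to 0.6).
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(32L, 32L, 32L), nCases = 6L, seed = 1L,
                        noiseSigma = 0.05,
                        contrastTable = defaultContrastTable(),
                        tumorRadiusRange = c(0.35, 0.6)) {
  new("PhantomSpec", shape = as.integer(shape), nCases = as.integer(nCases),
      seed = as.integer(seed), noiseSigma = noiseSigma,
      contrastTable = contrastTable, tumorRadiusRange = tumorRadiusRange)
}

# smooth random field on the voxel grid: a few random cosine modes,
# normalized to roughly unit amplitude
smoothField <- function(shape, nModes = 6L, maxFreq = 2.5) {
  g <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  f <- array(0, dim = shape)
  for (m in seq_len(nModes)) {
    k <- stats::runif(3, 0.5, maxFreq)
    ph <- stats::runif(3, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * outer(outer(cos(2 * pi * k[1] * g[[1]] + ph[1]),
                             cos(2 * pi * k[2] * g[[2]] + ph[2])),
                       cos(2 * pi * k[3] * g[[3]] + ph[3]))
  }
  f / sqrt(nModes / 2)
}

#' Generate one synthetic multimodal case
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param caseSeed RNG seed for this case (derived from the spec seed by
#'   \code{\link{makePhantomDataset}}).
#' @param caseId identifier for the generated case.
#' @return a \linkS4class{MultimodalCase} with the four source modalities
#'   and a label volume.
#' @export
makePhantomCase <- function(spec, caseSeed = spec@seed,
                            caseId = sprintf("phantom_%03d", caseSeed)) {
  stopifnot(is(spec, "PhantomSpec"))
  withSeed(caseSeed, function() {
    d <- spec@shape
    ax <- lapply(1:3, function(a) seq_len(d[a]) - (d[a] + 1) / 2)
    semi <- 0.42 * d
    # normalized squared ellipsoid coordinate of every voxel
    rho2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
                  (ax[[3]] / semi[3])^2, "+")
    brain <- rho2 <= 1
    # tumor center placed well inside the brain
    ctr <- stats::runif(3, -0.25, 0.25) * semi
    rWT <- stats::runif(1, spec@tumorRadiusRange[1],
                        spec@tumorRadiusRange[2]) * min(semi)
    aniso <- stats::runif(3, 0.85, 1.15)
    tr2 <- outer(outer(((ax[[1]] - ctr[1]) / (rWT * aniso[1]))^2,
                       ((ax[[2]] - ctr[2]) / (rWT * aniso[2]))^2, "+"),
                 ((ax[[3]] - ctr[3]) / (rWT * aniso[3]))^2, "+")
    # irregular boundary: one smooth perturbation shared by all shells,
    # so the nesting of the thresholded regions is preserved
    pert <- 0.12 * smoothField(d)
    tshape <- sqrt(tr2) + pert
    wt <- brain & (tshape < 1)
    tc <- brain & (tshape < 0.72)
    et <- brain & (tshape < 0.45)
    if (!any(wt)) stop("phantom spec error: tumor fell outside the brain support")
    lab <- array(0L, dim = d)
    lab[wt] <- 2L   # edema shell
    lab[tc] <- 1L   # necrosis / non-enhancing core
    lab[et] <- 4L   # enhancing core
    tissue <- array(1L, dim = d)  # 1 brain, 2 ed, 3 ncr, 4 et
    tissue[lab == 2L] <- 2L
    tissue[lab == 1L] <- 3L
    tissue[lab == 4L] <- 4L
    ct <- spec@contrastTable
    vols <- list()
    anat <- 1 + 0.08 * smoothField(d)  # shared smooth anatomy modulation
    for (m in rownames(ct)) {
      v <- ct[m, ][tissue]
      dim(v) <- d
      v <- v * anat +
        stats::rnorm(prod(d), sd = spec@noiseSigma)
      v[!brain] <- 0
      v[brain] <- pmax(v[brain], 1e-3)  # keep the support exactly the brain
      vols[[m]] <- BrainVolume(v)
    }
    MultimodalCase(caseId = caseId, volumes = vols,
                   label = LabelVolume(lab))
  })
}

#' Generate a phantom dataset in the BraTS directory layout
#'
#' Writes \code{spec@nCases} cases with per-case seeds derived from the
#' spec seed, each readable by \code{\link{readCase}}.  Calling the
#' function twice with the same spec produces identical files.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param dir output directory (one sub-directory per case).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the list of generated \linkS4class{MultimodalCase}s.
#' @export
makePhantomDataset <- function(spec, dir, overwrite = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  if (dir.exists(dir) && !overwrite) {
    stop(sprintf("output directory '%s' exists; use overwrite = TRUE", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- lapply(seq_len(spec@nCases), function(i) {
    cs <- (spec@seed %% 1000000L) * 1000L + i  # keep derived seeds in integer range
    case <- makePhantomCase(spec, caseSeed = cs,
                            caseId = sprintf("phantom_%03d", i))
    writeCase(case, dir)
    case
  })
  invisible(cases)
}
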