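# Case IO, normalization, label/region conversion, window extraction.

test_that("z-score normalization standardizes the non-zero support only", {
  v <- BrainVolume(array(c(0, 2, 4, 0, 0, 0, 2, 4), dim = c(2, 2, 2)))
  out <- volData(zscoreNormalize(v))
  expect_equal(out[volData(v) == 2], rep(-1, 2))
  expect_equal(out[volData(v) == 4], rep(1, 2))
  expect_true(all(out[volData(v) == 0] == 0))

  # already standardized -> unchanged; and recomputed moments are 0/1
  set.seed(1)
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  x[1:3, , ] <- 0
  v2 <- zscoreNormalize(BrainVolume(x))
  v3 <- zscoreNormalize(v2)
  expect_equal(volData(v3), volData(v2), tolerance = 1e-6)
  support <- volData(v2) != 0
  vals <- volData(v2)[support]
  expect_equal(sum(vals) / length(vals), 0, tolerance = 1e-5)
  expect_equal(sqrt(sum((vals - mean(vals))^2) / length(vals)), 1,
               tolerance = 1e-5)
})

test_that("z-score normalization is invariant to affine rescaling of the support", {
  set.seed(2)
  x <- array(runif(6^3, 1, 5), dim = c(6, 6, 6))
  x[1:2, , ] <- 0
  a <- 3.7; b <- -1.2
  y <- x
  y[x != 0] <- a * x[x != 0] + b
  expect_equal(volData(zscoreNormalize(BrainVolume(y))),
               volData(zscoreNormalize(BrainVolume(x))), tolerance = 1e-10)
})

test_that("degenerate volumes are rejected by normalization", {
  expect_error(zscoreNormalize(BrainVolume(array(0, dim = c(4, 4, 4)))),
               "all-zero")
  expect_error(zscoreNormalize(BrainVolume(array(rep(c(0, 3), 32),
                                                 dim = c(4, 4, 4)))),
               "standard deviation")
})

test_that("label volumes convert to nested region masks and back", {
  lab <- LabelVolume(array(c(0L, 1L, 2L, 4L, 0L, 4L, 2L, 1L),
                           dim = c(2, 2, 2)))
  r <- labelsToRegions(lab)
  # label 4: member of all three regions; label 2: wt only; label 1: wt+tc
  expect_equal(regionMask(r, "wt")[volData(lab) == 4], rep(1, 2))
  expect_equal(regionMask(r, "tc")[volData(lab) == 4], rep(1, 2))
  expect_equal(regionMask(r, "et")[volData(lab) == 4], rep(1, 2))
  expect_equal(regionMask(r, "tc")[volData(lab) == 2], rep(0, 2))
  expect_equal(regionMask(r, "et")[volData(lab) == 1], rep(0, 2))
  expect_true(all(regionMask(r, "et") <= regionMask(r, "tc")))
  expect_true(all(regionMask(r, "tc") <= regionMask(r, "wt")))
  expect_equal(volData(regionsToLabels(r)), volData(lab))

  zero <- labelsToRegions(LabelVolume(array(0L, dim = c(3, 3, 3))))
  expect_equal(sum(regionMask(zero, "wt")), 0)

  expect_error(LabelVolume(array(3L, dim = c(2, 2, 2))), "0,1,2,4")
})

test_that("region/label round trip is the identity on random nested masks", {
  set.seed(3)
  for (i in 1:10) {
    r <- randomNestedMasks(c(5, 6, 4))
    lab <- regionsToLabels(r)
    r2 <- labelsToRegions(lab)
    expect_equal(regionMask(r2, "wt"), regionMask(r, "wt"))
    expect_equal(regionMask(r2, "tc"), regionMask(r, "tc"))
    expect_equal(regionMask(r2, "et"), regionMask(r, "et"))
  }
  # non-nested masks are a contract violation
  expect_error(RegionMasks(wt = array(0, c(2, 2, 2)),
                           tc = array(1, c(2, 2, 2)),
                           et = array(0, c(2, 2, 2))), "contained")
})

test_that("maximum-tumor window matches the exhaustive oracle", {
  # single tumor voxel: the chosen window must contain it
  m <- array(0, dim = c(10, 10, 10)); m[6, 6, 6] <- 1
  ws <- maxTumorWindow(m, c(2, 2, 2))
  o <- windowOrigin(ws)
  expect_true(all(o <= 5) && all(o + 2 > 5))
  expect_equal(sum(cropWindow(m, ws)), 1)

  # all-zero mask: lexicographic tie-break picks the origin
  expect_equal(windowOrigin(maxTumorWindow(array(0, c(8, 8, 8)), c(3, 3, 3))),
               c(0L, 0L, 0L))

  set.seed(4)
  for (i in 1:8) {
    d <- sample(8:16, 3, replace = TRUE)
    m <- array(as.numeric(runif(prod(d)) > 0.92), dim = d)
    size <- sample(3:5, 3, replace = TRUE)
    ws <- maxTumorWindow(m, size)
    oracle <- bruteMaxWindow(m, size)
    expect_equal(sum(cropWindow(m, ws)), oracle$count)
    expect_equal(windowOrigin(ws), as.integer(oracle$origin))
  }

  expect_error(maxTumorWindow(array(0, c(4, 4, 4)), c(5, 4, 4)), "exceeds")
})

test_that("cases round-trip through the BraTS directory layout", {
  case <- tinyPhantomCases(1)[[1]]
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-5, 10, 3)
  case@volumes[["t1"]]@affine <- aff
  dir <- withr::local_tempdir()
  writeCase(case, dir)
  back <- readCase(file.path(dir, caseId(case)))
  expect_equal(modalities(back), modalities(case))
  for (m in modalities(case)) {
    expect_equal(volData(getVolume(back, m)), volData(getVolume(case, m)),
                 tolerance = 1e-7)
  }
  expect_equal(volAffine(getVolume(back, "t1"))[1:3, 4], c(-5, 10, 3))
  expect_equal(volData(caseLabel(back)), volData(caseLabel(case)))

  # missing modality is named in the error
  unlink(file.path(dir, caseId(case),
                   sprintf("%s_flair.nii.gz", caseId(case))))
  expect_error(readCase(file.path(dir, caseId(case))), "flair")
})

test_that("label files with out-of-domain values are rejected on read", {
  case <- tinyPhantomCases(1)[[1]]
  dir <- withr::local_tempdir()
  writeCase(case, dir)
  bad <- volData(caseLabel(case))
  bad[1, 1, 1] <- 3L
  img <- RNifti::asNifti(bad)
  RNifti::writeNifti(img, file.path(dir, caseId(case),
                                    sprintf("%s_seg.nii.gz", caseId(case))))
  expect_error(readCase(file.path(dir, caseId(case))), "0,1,2,4")
})

test_that("padding embeds a volume symmetrically and reports its offset", {
  x <- array(1, dim = c(3, 3, 3))
  p <- padToShape(x, c(5, 7, 3))
  expect_equal(dim(p$data), c(5L, 7L, 3L))
  expect_equal(sum(p$data), 27)
  expect_equal(p$offset, c(1L, 2L, 0L))
  expect_equal(p$data[p$offset[1] + 1:3, p$offset[2] + 1:3, 1:3], x)
})
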