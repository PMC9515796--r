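# Losses, schedule, stage networks, pipeline assembly, post-processing.

test_that("Dice and BCE losses reproduce their closed forms", {
  expect_equal(diceLoss(rep(1, 8), rep(1, 8), eps = 1e-5),
               1 - 16 / (16 + 1e-5))
  expect_equal(diceLoss(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(diceLoss(c(1, 0), c(1, 1)), 1 / 3, tolerance = 1e-5)

  g <- c(1, 0, 1, 1, 0)
  expect_lt(bceLoss(g, g), 1e-5)
  expect_equal(bceLoss(rep(0.5, 12), rbinom(12, 1, 0.5)), log(2))
  set.seed(20)
  p <- runif(20); gg <- rbinom(20, 1, 0.4)
  expect_equal(bceLoss(p, gg),
               -mean(gg * log(p) + (1 - gg) * log(1 - p)), tolerance = 1e-9)
})

test_that("the region loss sums Dice + lambda * BCE over regions", {
  set.seed(21)
  p <- list(tc = runif(27), et = runif(27))
  g <- list(tc = rbinom(27, 1, 0.4), et = rbinom(27, 1, 0.2))
  cfg <- segLossConfig(lambda = 0.5)
  manual <- diceLoss(p$tc, g$tc) + 0.5 * bceLoss(p$tc, g$tc) +
    diceLoss(p$et, g$et) + 0.5 * bceLoss(p$et, g$et)
  expect_equal(segLoss(p, g, cfg), manual, tolerance = 1e-9)
  expect_equal(segLoss(p, g, segLossConfig(lambda = 0)),
               diceLoss(p$tc, g$tc) + diceLoss(p$et, g$et), tolerance = 1e-9)
  perfect <- segLoss(g, g, cfg)
  expect_lt(perfect, 1e-4)
})

test_that("the loss falls monotonically as predictions approach the target", {
  set.seed(22)
  p <- runif(50, 0.05, 0.95)
  g <- rbinom(50, 1, 0.5)
  path <- sapply(seq(0, 1, by = 0.1), function(t)
    segLoss(list((1 - t) * p + t * g), list(g)))
  expect_true(all(diff(path) < 1e-9))
  # and is permutation-invariant over voxels
  o <- sample(50)
  expect_equal(segLoss(list(p[o]), list(g[o])), segLoss(list(p), list(g)))
})

test_that("the learning-rate schedule follows the polynomial decay", {
  expect_equal(lrSchedule(0, 300), 1e-4)
  expect_equal(lrSchedule(300, 300), 0)
  expect_equal(lrSchedule(150, 300), 1e-4 * 0.5^0.9, tolerance = 1e-12)
  expect_equal(lrSchedule(150, 300), 5.359e-5, tolerance = 1e-3)
  # monotone decreasing over the whole schedule
  lrs <- lrSchedule(0:300, 300)
  expect_true(all(diff(lrs) < 0))
})

test_that("stage networks have the prescribed interfaces", {
  cfg1 <- stageConfig(1, cropSize = c(8, 8, 8), depth = 2L, channels = 8L)
  expect_equal(cfg1@inputModalities, c("t2", "flair", "t2-flair"))
  expect_equal(cfg1@outputRegions, "wt")
  m1 <- buildStageNet(cfg1, msffConfig(3, channels = 8L), seed = 1)
  set.seed(23)
  x <- lapply(1:3, function(i) array(rnorm(8 * 8 * 16), dim = c(8, 8, 16)))
  p <- stageForward(m1, x)
  expect_named(p, "wt")
  expect_equal(dim(p$wt), c(8L, 8L, 16L))
  expect_true(all(p$wt >= 0 & p$wt <= 1))

  cfg2 <- stageConfig(2, cropSize = c(8, 8, 8), depth = 2L, channels = 8L)
  expect_equal(length(cfg2@inputModalities), 6)
  m2 <- buildStageNet(cfg2, msffConfig(6, channels = 8L), seed = 2)
  x6 <- lapply(1:6, function(i) array(rnorm(8^3), dim = c(8, 8, 8)))
  p2 <- stageForward(m2, x6)
  expect_named(p2, c("tc", "et"))
  expect_equal(dim(p2$tc), c(8L, 8L, 8L))

  # crop size must divide 2^(depth-1)
  expect_error(stageConfig(1, cropSize = c(10, 10, 10), depth = 3L),
               "divisible")
  expect_error(stageForward(m1, lapply(1:3, function(i)
    array(0, dim = c(7, 8, 8)))), "divisible")
})

test_that("full-scale stage defaults follow the training protocol", {
  c1 <- stageConfig(1)
  expect_equal(c1@cropSize, c(128L, 192L, 160L))
  c2 <- stageConfig(2)
  expect_equal(c2@cropSize, c(128L, 128L, 128L))
  expect_equal(c2@depth, 4L)
  expect_equal(c2@channels, 16L)
})

test_that("prediction with ground-truth-stubbed stages is the identity", {
  case <- tinyPhantomCases(1)[[1]]
  gt <- labelsToRegions(caseLabel(case))
  stub1 <- function(cs, window) {
    list(wt = regionMask(labelsToRegions(caseLabel(cs)), "wt"))
  }
  stub2 <- function(cs, window) {
    r <- labelsToRegions(caseLabel(cs))
    list(tc = cropWindow(regionMask(r, "tc"), window),
         et = cropWindow(regionMask(r, "et"), window))
  }
  out <- predictCase(case, stub1, stub2, list())
  expect_equal(volData(out$labels), volData(caseLabel(case)))
  expect_true(all(volData(out$labels) %in% c(0L, 1L, 2L, 4L)))
  expect_true(all(regionMask(out$regions, "et") <=
                    regionMask(out$regions, "tc")))
  expect_true(all(regionMask(out$regions, "tc") <=
                    regionMask(out$regions, "wt")))
})

test_that("an empty stage-1 prediction yields an empty labeling at the origin", {
  case <- tinyPhantomCases(1)[[1]]
  stubEmpty <- function(cs, window) {
    list(wt = array(0, dim = dim(volData(getVolume(cs, "t1")))))
  }
  stub2 <- function(cs, window) {
    r <- labelsToRegions(caseLabel(cs))
    list(tc = cropWindow(regionMask(r, "tc"), window),
         et = cropWindow(regionMask(r, "et"), window))
  }
  out <- predictCase(case, stubEmpty, stub2, list(), window2 = c(8, 8, 8))
  expect_equal(windowOrigin(out$window), c(0L, 0L, 0L))
  expect_equal(sum(volData(out$labels)), 0)
})

test_that("small enhancing-tumor predictions are relabeled as necrosis", {
  mk <- function(nEt) {
    x <- array(0L, dim = c(10, 10, 10))
    if (nEt > 0) x[seq_len(nEt)] <- 4L
    LabelVolume(x)
  }
  out <- postprocessEt(mk(499), threshold = 500L)
  expect_equal(sum(volData(out) == 4L), 0)
  expect_equal(sum(volData(out) == 1L), 499)
  expect_equal(volData(postprocessEt(mk(500))), volData(mk(500)))
  expect_equal(volData(postprocessEt(mk(0))), volData(mk(0)))
  # desk-scale threshold
  out5 <- postprocessEt(mk(4), threshold = 5L)
  expect_equal(sum(volData(out5) == 4L), 0)
})

test_that("training rejects unusable datasets", {
  cfg <- stageConfig(1, cropSize = c(8, 8, 8), depth = 1L, channels = 4L)
  expect_error(trainStage(list(), cfg), "empty")
  case <- tinyPhantomCases(1)[[1]]
  case@label <- NULL
  expect_error(trainStage(list(case), cfg), "label")
})
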