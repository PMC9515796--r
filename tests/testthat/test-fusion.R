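# Pixel-level fusion: architecture bookkeeping, SSIM, loss, convexity.

test_that("parameter counts match a layer-by-layer tally", {
  net <- pifnetInit("t2+flair", channels = 32L, seed = 1)
  # first convolution: 1 input channel, 32 filters of 3^3, one bias each
  expect_equal(length(net@params$branch1$conv$w$value) +
                 length(net@params$branch1$conv$b$value), 896)
  # independent tally: two branches (conv + residual pair at 32), one
  # residual pair at 64, 64->32 and 32->1 reductions
  convP <- function(cin, cout) 27 * cin * cout + cout
  branch <- convP(1, 32) + 2 * convP(32, 32)
  expected <- 2 * branch + 2 * convP(64, 64) + convP(64, 32) + convP(32, 1)
  expect_equal(paramCount(net), expected)
})

test_that("the weight mask drives a convex combination of the sources", {
  set.seed(5)
  net <- pifnetInit("t2+flair", channels = 4L, seed = 2)
  s1 <- array(runif(10^3), dim = c(10, 10, 10))
  s2 <- array(runif(10^3), dim = c(10, 10, 10))
  # force the mask to 1 via a huge final bias: fused == s1 exactly
  net@params$conv7$b$value <- 1e4
  out <- pifnetForward(net, s1, s2)
  expect_equal(out$fused, s1, tolerance = 1e-12)
  # zero final layer weights and bias: sigmoid(0) = 0.5, fused = mean
  net@params$conv7$w$value[] <- 0
  net@params$conv7$b$value <- 0
  out <- pifnetForward(net, s1, s2)
  expect_equal(out$mask, array(0.5, dim = dim(s1)))
  expect_equal(out$fused, (s1 + s2) / 2)
})

test_that("fused voxels stay inside the source envelope and zeros stay zero", {
  set.seed(6)
  for (i in 1:5) {
    net <- pifnetInit("t1c+t2", channels = 3L, seed = i)
    # random rescaling makes the parameters arbitrary, not just He draws
    for (p in FuseSeg:::agParamList(net@params)) {
      p$value <- p$value * runif(1, 0.2, 5) + rnorm(length(p$value), sd = 0.1)
    }
    d <- c(9, 9, 9)
    s1 <- array(runif(prod(d)), dim = d)
    s2 <- array(runif(prod(d)), dim = d)
    bg <- array(runif(prod(d)) < 0.3, dim = d)
    s1[bg] <- 0; s2[bg] <- 0
    out <- pifnetForward(net, s1, s2)
    expect_true(all(out$mask >= 0 & out$mask <= 1))
    expect_true(all(out$fused >= pmin(s1, s2) - 1e-12))
    expect_true(all(out$fused <= pmax(s1, s2) + 1e-12))
    expect_true(all(out$fused[bg] == 0))
  }
})

test_that("3D SSIM matches the brute-force window oracle", {
  set.seed(7)
  expect_error(ssim3d(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)), win = 7),
               "window")
  for (i in 1:6) {
    d <- sample(7:12, 3, replace = TRUE)
    x <- array(runif(prod(d)), dim = d)
    y <- array(runif(prod(d)), dim = d)
    expect_equal(ssim3d(x, x), 1, tolerance = 1e-6)
    expect_equal(ssim3d(x, y), ssim3d(y, x), tolerance = 1e-6)
    expect_equal(ssim3d(x, y), bruteSsim3d(x, y), tolerance = 1e-6)
    # a smaller window too
    expect_equal(ssim3d(x, y, win = 5), bruteSsim3d(x, y, win = 5),
                 tolerance = 1e-6)
  }
})

test_that("the composite fusion loss assembles its printed closed forms", {
  d <- c(8, 8, 8)
  s <- array(runif(prod(d)), dim = d)
  z <- fusionLoss(s, s, s, fusionLossConfig("t2+flair"))
  expect_equal(z$pixel, 0)
  expect_equal(z$ssim, 0, tolerance = 1e-9)
  expect_equal(z$pif, 0, tolerance = 1e-6)

  # 2^3 toy volumes: F = S1 = ones, S2 = zeros, beta = 2 -> pixel loss 16
  ones2 <- array(1, dim = c(2, 2, 2)); zeros2 <- array(0, dim = c(2, 2, 2))
  cfg2 <- fusionLossConfig("t1c+t2")  # beta = gamma = 2
  expect_equal(cfg2@beta, 2); expect_equal(cfg2@gamma, 2)
  expect_equal(pixelLoss(ones2, ones2, zeros2, beta = 2), 16)

  # alpha = 450 composition on random volumes
  set.seed(8)
  f <- array(runif(prod(d)), dim = d)
  s2 <- array(runif(prod(d)), dim = d)
  cfg <- fusionLossConfig("t2+flair", alpha = 450)
  got <- fusionLoss(f, s, s2, cfg)
  pix <- sum((f - s)^2) + cfg@beta * sum((f - s2)^2)
  ssm <- cfg@gamma * (1 - ssim3d(f, s)) + (1 - ssim3d(f, s2))
  expect_equal(got$pif, pix + 450 * ssm, tolerance = 1e-9)
  expect_true(all(c(got$pif, got$pixel, got$ssim) >= 0))
})

test_that("raising the pixel weight on S2 pulls the optimum toward S2", {
  # constant sources a, b and a constant mask m: the pixel loss is a
  # scalar quadratic in F = m a + (1-m) b, minimized at F* = (a + beta b)
  # / (1 + beta); larger beta moves F* toward b
  a <- 1; b <- 0
  fstar <- function(beta) (a + beta * b) / (1 + beta)
  expect_lt(abs(fstar(2) - b), abs(fstar(1) - b))
  # numeric minimization of the package loss agrees with the closed form
  for (beta in c(1, 2)) {
    obj <- function(f) sum((f - a)^2) + beta * sum((f - b)^2)
    opt <- optimize(function(f) obj(f), c(0, 1))
    expect_equal(opt$minimum, fstar(beta), tolerance = 1e-4)
  }
})

test_that("fusing a case adds exactly the requested modalities", {
  cases <- tinyPhantomCases(1)
  nets <- list(
    "t2+flair" = pifnetInit("t2+flair", channels = 3L, seed = 1),
    "t1c+t2" = pifnetInit("t1c+t2", channels = 3L, seed = 2),
    "t1c+flair" = pifnetInit("t1c+flair", channels = 3L, seed = 3))
  c1 <- fuseCase(cases[[1]], nets, "t2+flair")
  expect_setequal(modalities(c1), c(modalities(cases[[1]]), "t2-flair"))
  c2 <- fuseCase(cases[[1]], nets, c("t1c+t2", "t1c+flair"))
  expect_setequal(modalities(c2),
                  c(modalities(cases[[1]]), "t1c-t2", "t1c-flair"))
  expect_identical(volData(getVolume(c2, "t2")),
                   volData(getVolume(cases[[1]], "t2")))
  expect_error(fuseCase(cases[[1]], nets["t2+flair"], "t1c+t2"), "pairing")

  # fused volumes survive the disk round trip
  dir <- withr::local_tempdir()
  writeCase(c1, dir)
  back <- readCase(file.path(dir, caseId(c1)))
  expect_true("t2-flair" %in% modalities(back))
  expect_equal(volData(getVolume(back, "t2-flair")),
               volData(getVolume(c1, "t2-flair")), tolerance = 1e-7)
})
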