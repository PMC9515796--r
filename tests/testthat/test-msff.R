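# Modality-selection feature fusion: shapes, attention normalization,
# limit cases, differentiability.

test_that("feature extraction yields 16 channels with preserved shape", {
  cfg <- msffConfig(3)
  params <- msffInit(cfg, seed = 1)
  vols <- lapply(1:3, function(i) array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)))
  u <- extractFeatures(vols, params, cfg)
  expect_length(u, 3)
  for (ui in u) expect_equal(dim(ui), c(5L, 6L, 7L, 16L))
  # zero input with zero bias gives zero features (linearity)
  z <- extractFeatures(list(array(0, c(5, 6, 7)), vols[[2]], vols[[3]]),
                       params, cfg)
  expect_equal(sum(abs(z[[1]])), 0)
  expect_error(extractFeatures(vols[1:2], params, cfg), "expected 3")
})

test_that("merge, pooling and recombination match their definitions", {
  set.seed(10)
  d <- c(4, 4, 4, 6)
  u <- lapply(1:3, function(i) array(rnorm(prod(d)), dim = d))
  expect_equal(mergeSum(u), u[[1]] + u[[2]] + u[[3]])
  expect_equal(mergeSum(u[1]), u[[1]])
  const <- lapply(c(1.5, -2, 0.25), function(c) array(c, dim = d))
  expect_equal(mergeSum(const), array(-0.25, dim = d))

  expect_equal(globalPool(array(2, dim = d)), rep(2, 6))
  one <- array(rnorm(6), dim = c(1, 1, 1, 6))
  expect_equal(globalPool(one), as.vector(one))
  expect_equal(globalPool(u[[1]]),
               apply(u[[1]], 4, mean), tolerance = 1e-6)

  # uniform attention = arithmetic mean; near-one-hot recovers a branch
  att <- matrix(1 / 3, 3, 6)
  expect_equal(fuseFeatures(u, att), (u[[1]] + u[[2]] + u[[3]]) / 3)
  hot <- rbind(rep(1, 6), rep(0, 6), rep(0, 6))
  expect_equal(fuseFeatures(u, hot), u[[1]])
  # random convex attention keeps V inside the element-wise envelope
  w <- matrix(runif(18), 3, 6); w <- sweep(w, 2, colSums(w), "/")
  v <- fuseFeatures(u, w)
  lo <- pmin(u[[1]], u[[2]], u[[3]]); hi <- pmax(u[[1]], u[[2]], u[[3]])
  expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
})

test_that("attention is a cross-branch softmax per channel", {
  cfg <- msffConfig(3)
  params <- msffInit(cfg, seed = 2)
  set.seed(11)
  # normalization holds for arbitrary pooled vectors and parameters
  for (i in 1:10) {
    s <- rnorm(16, sd = 3)
    att <- attentionWeights(s, params, cfg)
    expect_equal(dim(att), c(3L, 16L))
    expect_equal(colSums(att), rep(1, 16), tolerance = 1e-12)
    expect_true(all(att > 0 & att < 1))
  }
  # equal logits (zeroed excitations) -> uniform 1/N
  for (i in 1:3) {
    params$excite[[i]]$w$value[] <- 0
    params$excite[[i]]$b$value[] <- 0
  }
  expect_equal(attentionWeights(rnorm(16), params, cfg),
               matrix(1 / 3, 3, 16))
  # hand-computed two-branch softmax: logits 0 and log 3 -> 0.25 / 0.75
  cfg2 <- msffConfig(2)
  p2 <- msffInit(cfg2, seed = 3)
  for (i in 1:2) p2$excite[[i]]$w$value[] <- 0
  p2$excite[[1]]$b$value[] <- 0
  p2$excite[[2]]$b$value[] <- log(3)
  att2 <- attentionWeights(rnorm(16), p2, cfg2)
  expect_equal(att2[1, ], rep(0.25, 16))
  expect_equal(att2[2, ], rep(0.75, 16))
  # single branch: attention identically 1, module reduces to its extractor
  cfg1 <- msffConfig(1)
  p1 <- msffInit(cfg1, seed = 4)
  vol <- list(array(rnorm(4^3), c(4, 4, 4)))
  out1 <- msffForward(vol, p1, cfg1)
  expect_equal(out1$attention, matrix(1, 1, 16))
  expect_equal(out1$fused, extractFeatures(vol, p1, cfg1)[[1]])
})

test_that("the composed forward pass is consistent and permutation-equivariant", {
  cfg <- msffConfig(3)
  params <- msffInit(cfg, seed = 5)
  set.seed(12)
  vols <- lapply(1:3, function(i) array(rnorm(4^3), dim = c(4, 4, 4)))
  out <- msffForward(vols, params, cfg)
  expect_equal(dim(out$fused), c(4L, 4L, 4L, 16L))
  # the training-graph forward produces the same numbers
  node <- FuseSeg:::msffForwardNode(vols, params, cfg)
  expect_equal(node$fused$value, out$fused, tolerance = 1e-12)
  # permuting modalities together with their branch parameters leaves V fixed
  perm <- c(3, 1, 2)
  paramsPerm <- params
  paramsPerm$extract <- params$extract[perm]
  paramsPerm$excite <- params$excite[perm]
  outPerm <- msffForward(vols[perm], paramsPerm, cfg)
  expect_equal(outPerm$fused, out$fused, tolerance = 1e-12)
})

test_that("gradients of the module match finite differences", {
  cfg <- msffConfig(3, channels = 16L, reduction = 4L)
  params <- msffInit(cfg, seed = 6)
  set.seed(13)
  vols <- lapply(1:3, function(i) array(rnorm(4^3), dim = c(4, 4, 4)))
  tgt <- array(rnorm(4^3 * 16), dim = c(4, 4, 4, 16))
  lossFn <- function() {
    v <- FuseSeg:::msffForwardNode(vols, params, cfg)$fused
    FuseSeg:::agNode(sum((v$value - tgt)^2), parents = list(v),
                     backward = function(n) {
                       FuseSeg:::agAccum(v, n$grad * 2 * (v$value - tgt))
                     })
  }
  FuseSeg:::agZeroGrad(params)
  loss <- lossFn()
  FuseSeg:::agBackward(loss)
  flat <- FuseSeg:::agParamList(params)
  eps <- 1e-6
  for (p in flat) {
    idx <- sample(length(p$value), min(4, length(p$value)))
    for (j in idx) {
      v0 <- p$value[j]
      p$value[j] <- v0 + eps; lp <- lossFn()$value
      p$value[j] <- v0 - eps; lm <- lossFn()$value
      p$value[j] <- v0
      fd <- (lp - lm) / (2 * eps)
      an <- if (is.null(p$grad)) 0 else p$grad[j]
      expect_true(is.finite(an))
      expect_equal(an, fd, tolerance = 1e-3)
    }
  }
})
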