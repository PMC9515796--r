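# Independent brute-force oracles and small fixture builders used across
# the suite.  The oracles deliberately use plain-R loops over definitions
# rather than any code path of the package.

# direct per-window SSIM: loops over every valid window position
bruteSsim3d <- function(x, y, win = 7L, k1 = 0.01, k2 = 0.03, L = 1) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  d <- dim(x)
  vals <- c()
  for (k in 1:(d[3] - win + 1)) for (j in 1:(d[2] - win + 1))
    for (i in 1:(d[1] - win + 1)) {
      wx <- x[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
      wy <- y[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
      mx <- mean(wx); my <- mean(wy)
      vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
      cxy <- mean(wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# exhaustive argmax over every window origin, first in (d,h,w) lexicographic
# order among ties
bruteMaxWindow <- function(mask, size) {
  d <- dim(mask)
  best <- -1; bestO <- c(0L, 0L, 0L)
  for (o1 in 0:(d[1] - size[1])) for (o2 in 0:(d[2] - size[2]))
    for (o3 in 0:(d[3] - size[3])) {
      s <- sum(mask[o1 + seq_len(size[1]), o2 + seq_len(size[2]),
                    o3 + seq_len(size[3])])
      if (s > best) { best <- s; bestO <- c(o1, o2, o3) }
    }
  list(origin = bestO, count = best)
}

# surface voxels: mask voxels with a 6-connected background neighbour
# (volume border counts as background)
bruteSurface <- function(m) {
  d <- dim(m)
  out <- NULL
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
      if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
      if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
    if (length(nb) < 6 || any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  out
}

bruteHd95 <- function(a, b, spacing = c(1, 1, 1), prob = 0.95) {
  if (sum(a) == 0 && sum(b) == 0) return(0)
  if (sum(a) == 0 || sum(b) == 0) return(373.1287)
  sa <- bruteSurface(a != 0); sb <- bruteSurface(b != 0)
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)),
                Vectorize(function(i, j)
                  sqrt(sum(((sa[i, ] - sb[j, ]) * spacing)^2))))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  max(quantile(dab, prob, names = FALSE), quantile(dba, prob, names = FALSE))
}

# random nested region masks on a small grid
randomNestedMasks <- function(d = c(6, 6, 6)) {
  base <- array(runif(prod(d)), dim = d)
  wt <- array(as.numeric(base > 0.5), dim = d)
  tc <- wt * array(as.numeric(runif(prod(d)) > 0.4), dim = d)
  et <- tc * array(as.numeric(runif(prod(d)) > 0.4), dim = d)
  RegionMasks(wt = wt, tc = tc, et = et)
}

# small phantom cases shared by the heavier tests
tinyPhantomCases <- function(n = 2, shape = c(16, 16, 16), seed = 42) {
  spec <- phantomSpec(shape = shape, nCases = n, seed = seed)
  lapply(seq_len(n), function(i)
    makePhantomCase(spec, caseSeed = seed * 100 + i,
                    caseId = sprintf("tiny_%02d", i)))
}
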