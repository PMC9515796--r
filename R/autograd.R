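# Reverse-mode automatic differentiation over dense numeric arrays.
#
# Each node is an environment holding a value, an accumulated gradient, its
# parent nodes and a backward closure.  Graphs are built eagerly during the
# forward pass; agBackward() runs the closures in reverse creation order.
# Only the handful of operations the fusion/attention/segmentation networks
# need are provided; every backward rule is exercised against finite
# differences in the test suite.

.agState <- new.env(parent = emptyenv())
.agState$id <- 0L

agNextId <- function() {
  .agState$id <- .agState$id + 1L
  .agState$id
}

agNode <- function(value, parents = list(), backward = NULL,
                   requires = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires <- if (is.null(requires)) {
    any(vapply(parents, function(p) p$requires, logical(1)))
  } else {
    requires
  }
  e$id <- agNextId()
  class(e) <- "agNode"
  e
}

#' Wrap a constant array (no gradient tracked)
#' @param x numeric array or vector
#' @keywords internal
agConst <- function(x) agNode(x, requires = FALSE)

#' Wrap a trainable parameter
#' @param x numeric array or vector of initial values
#' @keywords internal
agParam <- function(x) agNode(x, requires = TRUE)

agAccum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation from a scalar node
#' @param root scalar-valued `agNode`
#' @keywords internal
agBackward <- function(root) {
  # collect the reachable graph, then replay backward in creation order
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  root$grad <- 1
  for (n in nodes[ord]) {
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n)
  }
  invisible(NULL)
}

agZeroGrad <- function(params) {
  walk <- function(x) {
    if (inherits(x, "agNode")) x$grad <- NULL else lapply(x, walk)
    invisible(NULL)
  }
  walk(params)
  invisible(NULL)
}

#' Flatten a nested parameter list into a list of agParam nodes
#' @keywords internal
agParamList <- function(params) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "agNode")) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      lapply(x, walk)
    }
    invisible(NULL)
  }
  walk(params)
  out
}

# ---- primitive operations ------------------------------------------------

#' 3D convolution node (stride/padding as in the network tables)
#' @keywords internal
agConv3d <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- x$value
  if (length(dim(xv)) == 3L) dim(xv) <- c(dim(xv), 1L)
  y <- cpp_conv3d_fw(xv, dim(xv), w$value, dim(w$value), b$value,
                     as.integer(stride), as.integer(pad))
  agNode(y, parents = list(x, w, b), backward = function(n) {
    gr <- cpp_conv3d_bw(xv, dim(xv), w$value, dim(w$value), n$grad,
                        as.integer(stride), as.integer(pad),
                        need_dx = x$requires)
    if (x$requires) {
      dx <- gr$dx
      if (!is.null(dim(x$value)) && length(dim(x$value)) == 3L) {
        dim(dx) <- dim(x$value)
      }
      agAccum(x, dx)
    }
    agAccum(w, gr$dw)
    agAccum(b, gr$db)
  })
}

#' @keywords internal
agRelu <- function(x) {
  pos <- x$value > 0
  agNode(x$value * pos, parents = list(x), backward = function(n) {
    agAccum(x, n$grad * pos)
  })
}

#' @keywords internal
agSigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  agNode(s, parents = list(x), backward = function(n) {
    agAccum(x, n$grad * s * (1 - s))
  })
}

#' @keywords internal
agAdd <- function(x, y) {
  agNode(x$value + y$value, parents = list(x, y), backward = function(n) {
    agAccum(x, n$grad)
    agAccum(y, n$grad)
  })
}

#' Concatenate two feature blocks along the channel axis
#' @keywords internal
agConcatC <- function(x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(all(dx[1:3] == dy[1:3]))
  v <- array(0, dim = c(dx[1:3], dx[4] + dy[4]))
  v[, , , seq_len(dx[4])] <- x$value
  v[, , , dx[4] + seq_len(dy[4])] <- y$value
  agNode(v, parents = list(x, y), backward = function(n) {
    agAccum(x, n$grad[, , , seq_len(dx[4]), drop = FALSE])
    agAccum(y, n$grad[, , , dx[4] + seq_len(dy[4]), drop = FALSE])
  })
}

#' Global average pooling over the spatial axes -> channel vector
#' @keywords internal
agGap <- function(x) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  v <- colMeans(matrix(x$value, nrow = nvox, ncol = d[4]))
  agNode(v, parents = list(x), backward = function(n) {
    g <- matrix(rep(n$grad / nvox, each = nvox), nrow = nvox)
    dim(g) <- d
    agAccum(x, g)
  })
}

#' Fully connected map on a channel vector (1x1x1 convolution)
#' @keywords internal
agDense <- function(x, w, b) {
  v <- drop(x$value %*% w$value) + b$value
  agNode(v, parents = list(x, w, b), backward = function(n) {
    agAccum(x, drop(w$value %*% n$grad))
    agAccum(w, outer(x$value, n$grad))
    agAccum(b, n$grad)
  })
}

#' Cross-branch softmax over N channel vectors
#'
#' Takes a list of N logit vectors (length C) and returns the N x C matrix
#' of attention weights, normalized across branches for each channel.
#' @keywords internal
agBranchSoftmax <- function(tlist) {
  tm <- do.call(rbind, lapply(tlist, function(t) t$value))  # N x C
  tm <- sweep(tm, 2, apply(tm, 2, max))                     # stabilized
  e <- exp(tm)
  s <- sweep(e, 2, colSums(e), "/")
  agNode(s, parents = tlist, backward = function(n) {
    g <- n$grad
    dot <- colSums(g * s)
    dt <- s * sweep(g, 2, dot)
    for (i in seq_along(tlist)) agAccum(tlist[[i]], dt[i, ])
  })
}

#' Extract row i of a matrix-valued node as a vector node
#' @keywords internal
agRow <- function(x, i) {
  agNode(x$value[i, ], parents = list(x), backward = function(n) {
    g <- matrix(0, nrow = nrow(x$value), ncol = ncol(x$value))
    g[i, ] <- n$grad
    agAccum(x, g)
  })
}

#' Scale each channel of a feature block by a channel vector
#' @keywords internal
agScaleChannels <- function(u, s) {
  d <- dim(u$value)
  nvox <- prod(d[1:3])
  um <- matrix(u$value, nrow = nvox)
  v <- sweep(um, 2, s$value, "*")
  dim(v) <- d
  agNode(v, parents = list(u, s), backward = function(n) {
    gm <- matrix(n$grad, nrow = nvox)
    if (u$requires) {
      du <- sweep(gm, 2, s$value, "*")
      dim(du) <- d
      agAccum(u, du)
    }
    agAccum(s, colSums(gm * um))
  })
}

#' Instance normalization (per channel over the spatial grid, no affine)
#' @keywords internal
agInstanceNorm <- function(x, eps = 1e-5) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  xm <- matrix(x$value, nrow = nvox)
  mu <- colMeans(xm)
  v <- colMeans(sweep(xm, 2, mu)^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, "*")
  out <- xhat
  dim(out) <- d
  agNode(out, parents = list(x), backward = function(n) {
    g <- matrix(n$grad, nrow = nvox)
    gmean <- colMeans(g)
    gdot <- colMeans(g * xhat)
    dx <- sweep(g, 2, gmean) - sweep(xhat, 2, gdot, "*")
    dx <- sweep(dx, 2, inv, "*")
    dim(dx) <- d
    agAccum(x, dx)
  })
}

#' Nearest-neighbour 2x spatial upsampling
#' @keywords internal
agUpsample2 <- function(x) {
  d <- dim(x$value)
  idxD <- rep(seq_len(d[1]), each = 2)
  idxH <- rep(seq_len(d[2]), each = 2)
  idxW <- rep(seq_len(d[3]), each = 2)
  v <- x$value[idxD, idxH, idxW, , drop = FALSE]
  agNode(v, parents = list(x), backward = function(n) {
    g <- n$grad
    # sum 2x2x2 blocks back onto the coarse grid
    g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
          g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    g2 <- g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
          g1[, seq(2, 2 * d[2], 2), , , drop = FALSE]
    g3 <- g2[, , seq(1, 2 * d[3], 2), , drop = FALSE] +
          g2[, , seq(2, 2 * d[3], 2), , drop = FALSE]
    agAccum(x, g3)
  })
}

# ---- loss heads (analytic gradients) ------------------------------------

#' Convex-combination fusion F = m*s1 + (1-m)*s2 with constant sources
#' @keywords internal
agFuseMask <- function(m, s1, s2) {
  mv <- array(m$value, dim = dim(s1))
  v <- mv * s1 + (1 - mv) * s2
  agNode(v, parents = list(m), backward = function(n) {
    g <- n$grad * (s1 - s2)
    dim(g) <- dim(m$value)
    agAccum(m, g)
  })
}

#' Pixel loss  ||F - S1||_F^2 + beta * ||F - S2||_F^2
#' @keywords internal
agPixelLoss <- function(f, s1, s2, beta) {
  d1 <- f$value - s1
  d2 <- f$value - s2
  v <- sum(d1^2) + beta * sum(d2^2)
  agNode(v, parents = list(f), backward = function(n) {
    agAccum(f, n$grad * (2 * d1 + 2 * beta * d2))
  })
}

#' Mean local 3D SSIM between a node and a constant reference
#'
#' Uses a uniform cubic window at all valid positions; the analytic
#' gradient with respect to the first argument is accumulated.
#' @keywords internal
agSsim <- function(x, ref, win = 7L, k1 = 0.01, k2 = 0.03, L = 1) {
  st <- ssimStats(x$value, ref, win, k1, k2, L)
  agNode(st$mssim, parents = list(x), backward = function(n) {
    agAccum(x, n$grad * ssimGradX(st))
  })
}

#' Linear combination of scalar nodes: const + sum(coef_i * node_i)
#' @keywords internal
agScalarComb <- function(nodes, coefs, const = 0) {
  v <- const + sum(vapply(seq_along(nodes),
                          function(i) coefs[i] * nodes[[i]]$value,
                          numeric(1)))
  agNode(v, parents = nodes, backward = function(n) {
    for (i in seq_along(nodes)) agAccum(nodes[[i]], n$grad * coefs[i])
  })
}

#' Soft Dice loss node:  1 - 2*sum(p*g) / (sum(p^2) + sum(g^2) + eps)
#' @keywords internal
agDiceLoss <- function(p, g, eps = 1e-5) {
  pv <- as.vector(p$value)
  g <- as.vector(g)
  num <- 2 * sum(pv * g)
  den <- sum(pv^2) + sum(g^2) + eps
  v <- 1 - num / den
  agNode(v, parents = list(p), backward = function(n) {
    dp <- -(2 * g * den - num * 2 * pv) / den^2
    dim(dp) <- dim(p$value)
    agAccum(p, n$grad * dp)
  })
}

#' Binary cross-entropy loss node (mean over voxels, clipped probabilities)
#' @keywords internal
agBceLoss <- function(p, g, clip = 1e-7) {
  pv <- pmin(pmax(as.vector(p$value), clip), 1 - clip)
  g <- as.vector(g)
  nvox <- length(pv)
  v <- -mean(g * log(pv) + (1 - g) * log(1 - pv))
  agNode(v, parents = list(p), backward = function(n) {
    inside <- (as.vector(p$value) > clip) & (as.vector(p$value) < 1 - clip)
    dp <- -(g / pv - (1 - g) / (1 - pv)) / nvox * inside
    dim(dp) <- dim(p$value)
    agAccum(p, n$grad * dp)
  })
}

# ---- optimizer -----------------------------------------------------------

#' Create Adam optimizer state for a parameter list
#' @keywords internal
adamInit <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  flat <- agParamList(params)
  list(params = flat, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L,
       m = lapply(flat, function(p) p$value * 0),
       v = lapply(flat, function(p) p$value * 0))
}

#' One Adam update step in place; returns the updated optimizer state
#' @keywords internal
adamStep <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / corr1
    vhat <- opt$v[[i]] / corr2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# ---- parameter initialization -------------------------------------------

#' He-style initialization for a conv weight (kd,kh,kw,Cin,Cout)
#' @keywords internal
convInit <- function(k, cin, cout) {
  fanin <- k^3 * cin
  w <- array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fanin)),
             dim = c(k, k, k, cin, cout))
  list(w = agParam(w), b = agParam(numeric(cout)))
}

#' @keywords internal
denseInit <- function(cin, cout) {
  list(w = agParam(matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)),
                          cin, cout)),
       b = agParam(numeric(cout)))
}

#' Evaluate a function with a temporary RNG seed, restoring global state
#' @keywords internal
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
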