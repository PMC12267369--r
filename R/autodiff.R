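# Minimal tape-based reverse-mode automatic differentiation.
#
# A tape records nodes in creation order; backward() walks the tape in
# reverse, each node's closure scattering its gradient onto its parents.
# Values are plain numeric scalars, vectors, matrices, or 3-d arrays
# (H x W x C feature maps). Dense kernels (convolution, pooling, bilinear
# upsampling) are dispatched to compiled code.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- n
  n
}

ad_const <- function(tape, value) ad_node(tape, value)

ad_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  if (length(loss$value) != 1L) stop("backward() needs a scalar loss")
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

# Leaves for a flat named parameter list; grads read back with ad_grads().
ad_leaves <- function(tape, params) lapply(params, ad_const, tape = tape)

ad_grads <- function(leaves) {
  lapply(leaves, function(n) {
    if (is.null(n$grad)) {
      g <- n$value
      g[] <- 0
      g
    } else n$grad
  })
}

## ---- elementwise ----------------------------------------------------------

ad_add <- function(t, a, b)
  ad_node(t, a$value + b$value, function(g) { ad_acc(a, g); ad_acc(b, g) })

ad_sub <- function(t, a, b)
  ad_node(t, a$value - b$value, function(g) { ad_acc(a, g); ad_acc(b, -g) })

ad_mul <- function(t, a, b) {
  av <- a$value; bv <- b$value
  ad_node(t, av * bv, function(g) { ad_acc(a, g * bv); ad_acc(b, g * av) })
}

ad_div <- function(t, a, b) {
  av <- a$value; bv <- b$value
  ad_node(t, av / bv,
          function(g) { ad_acc(a, g / bv); ad_acc(b, -g * av / (bv * bv)) })
}

# a + constant / a * constant (constant not differentiated)
ad_addc <- function(t, a, k) ad_node(t, a$value + k, function(g) ad_acc(a, g))
ad_mulc <- function(t, a, k) ad_node(t, a$value * k, function(g) ad_acc(a, g * k))
ad_neg <- function(t, a) ad_mulc(t, a, -1)

ad_relu <- function(t, a) {
  keep <- a$value > 0
  ad_node(t, a$value * keep, function(g) ad_acc(a, g * keep))
}

ad_sigmoid <- function(t, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(t, s, function(g) ad_acc(a, g * s * (1 - s)))
}

ad_log <- function(t, a) {
  av <- a$value
  ad_node(t, log(av), function(g) ad_acc(a, g / av))
}

# elementwise power with constant exponent (base assumed >= 0)
ad_powc <- function(t, a, k) {
  av <- a$value
  ad_node(t, av^k, function(g) ad_acc(a, g * k * av^(k - 1)))
}

# clamp with zero gradient outside the open interval
ad_clip <- function(t, a, lo, hi) {
  av <- a$value
  inside <- (av > lo) & (av < hi)
  ad_node(t, pmin(pmax(av, lo), hi), function(g) ad_acc(a, g * inside))
}

ad_sum <- function(t, a) {
  shp <- a$value
  ad_node(t, sum(a$value), function(g) { shp[] <- g; ad_acc(a, shp) })
}

ad_mean <- function(t, a) {
  n <- length(a$value)
  shp <- a$value
  ad_node(t, sum(a$value) / n, function(g) { shp[] <- g / n; ad_acc(a, shp) })
}

## ---- linear algebra on token/feature matrices -----------------------------

ad_matmul <- function(t, a, b) {
  av <- a$value; bv <- b$value
  ad_node(t, av %*% bv, function(g) {
    ad_acc(a, g %*% t(bv))
    ad_acc(b, crossprod(av, g))
  })
}

# rows of X through an affine map: X %*% W + b (b broadcast over rows)
ad_linear_rows <- function(t, x, w, b) {
  xv <- x$value; wv <- w$value
  val <- xv %*% wv
  val <- sweep(val, 2L, b$value, "+")
  ad_node(t, val, function(g) {
    ad_acc(x, g %*% t(wv))
    ad_acc(w, crossprod(xv, g))
    ad_acc(b, colSums(g))
  })
}

# W %*% x + b for a plain channel vector x
ad_matvec <- function(t, w, x, b) {
  wv <- w$value; xv <- x$value
  ad_node(t, as.numeric(wv %*% xv + b$value), function(g) {
    ad_acc(w, outer(g, xv))
    ad_acc(x, as.numeric(crossprod(wv, g)))
    ad_acc(b, g)
  })
}

ad_softmax_rows <- function(t, a) {
  av <- a$value
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  s <- e / rowSums(e)
  ad_node(t, s, function(g) {
    dot <- rowSums(g * s)
    ad_acc(a, (g - dot) * s)
  })
}

# per-row layer normalisation with affine parameters (population variance)
ad_layernorm_rows <- function(t, x, gamma, beta, eps = 1e-6) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_node(t, val, function(g) {
    gg <- sweep(g, 2L, gamma$value, "*")
    s1 <- rowMeans(gg)
    s2 <- rowMeans(gg * xhat)
    ad_acc(x, inv * (gg - s1 - xhat * s2))
    ad_acc(gamma, colSums(g * xhat))
    ad_acc(beta, colSums(g))
  })
}

## ---- spatial ops (H x W x C arrays) ---------------------------------------

ad_conv2d <- function(t, x, w, b) {
  xv <- x$value; wv <- w$value
  ad_node(t, .cpp_conv2d_fw(xv, wv, b$value), function(g) {
    bw <- .cpp_conv2d_bw(xv, wv, g)
    ad_acc(x, bw$dx); ad_acc(w, bw$dw); ad_acc(b, bw$db)
  })
}

ad_maxpool2 <- function(t, x) {
  d <- dim(x$value)
  fw <- .cpp_maxpool2_fw(x$value)
  ad_node(t, fw$out,
          function(g) ad_acc(x, .cpp_maxpool2_bw(fw$idx, g, d[1], d[2], d[3])))
}

ad_upsample2 <- function(t, x) {
  d <- dim(x$value)
  ad_node(t, .cpp_upsample2_fw(x$value),
          function(g) ad_acc(x, .cpp_upsample2_bw(g, d[1], d[2], d[3])))
}

# global average pooling: H x W x C -> length-C channel statistics
ad_gap <- function(t, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  ad_node(t, as.numeric(colSums(matrix(x$value, n, d[3]))) / n, function(g) {
    ad_acc(x, array(rep(g / n, each = n), dim = d))
  })
}

# multiply each channel by a scalar gate (SE recalibration)
ad_chan_scale <- function(t, x, s) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  sb <- array(rep(s$value, each = n), dim = d)
  xv <- x$value
  ad_node(t, xv * sb, function(g) {
    ad_acc(x, g * sb)
    ad_acc(s, as.numeric(colSums(matrix(g * xv, n, d[3]))))
  })
}

# multiply every channel by one spatial map (similarity modulation)
ad_spat_scale <- function(t, x, m) {
  d <- dim(x$value)
  mb <- array(m$value, dim = d)
  xv <- x$value
  ad_node(t, xv * mb, function(g) {
    ad_acc(x, g * mb)
    gm <- rowSums(matrix(g * xv, d[1] * d[2], d[3]))
    ad_acc(m, array(gm, dim = d[1:2]))
  })
}

ad_concat_ch <- function(t, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  val <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ad_node(t, val, function(g) {
    ad_acc(a, g[, , seq_len(da[3]), drop = FALSE])
    ad_acc(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# per-episode (instance) normalisation over the spatial extent of each
# channel, followed by a learned affine map
ad_instnorm <- function(t, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  val <- sweep(xhat, 2L, gamma$value, "*")
  val <- sweep(val, 2L, beta$value, "+")
  ad_node(t, array(val, dim = d), function(g) {
    gm <- matrix(g, n, d[3])
    gg <- sweep(gm, 2L, gamma$value, "*")
    s1 <- colMeans(gg)
    s2 <- colMeans(gg * xhat)
    dx <- sweep(gg, 2L, s1) - sweep(xhat, 2L, s2, "*")
    dx <- sweep(dx, 2L, inv, "*")
    ad_acc(x, array(dx, dim = d))
    ad_acc(gamma, colSums(gm * xhat))
    ad_acc(beta, colSums(gm))
  })
}

# L2-normalise each pixel's channel vector: v / sqrt(sum(v^2) + eps)
ad_l2norm_ch <- function(t, x, eps = 1e-6) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  r <- sqrt(rowSums(xm * xm) + eps)
  xh <- xm / r
  ad_node(t, array(xh, dim = d), function(g) {
    gm <- matrix(g, n, d[3])
    dot <- rowSums(gm * xm)
    ad_acc(x, array(gm / r - xm * (dot / r^3), dim = d))
  })
}

ad_l2norm_vec <- function(t, x, eps = 1e-6) {
  xv <- x$value
  r <- sqrt(sum(xv * xv) + eps)
  ad_node(t, xv / r, function(g) {
    ad_acc(x, g / r - xv * (sum(g * xv) / r^3))
  })
}

# masked average pooling: P_c = sum_ij m_ij x_cij / (sum_ij m_ij + eps);
# the mask is a fixed binary array, not differentiated through
ad_masked_pool <- function(t, x, mask, eps = 1e-6) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  mv <- as.numeric(mask)
  denom <- sum(mv) + eps
  xm <- matrix(x$value, n, d[3])
  ad_node(t, as.numeric(crossprod(xm, mv)) / denom, function(g) {
    ad_acc(x, array(outer(mv, g / denom), dim = d))
  })
}

# per-pixel dot product of the channel vector with a fixed-length vector p
ad_chan_dot <- function(t, x, p) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  pv <- p$value
  ad_node(t, array(as.numeric(xm %*% pv), dim = d[1:2]), function(g) {
    gv <- as.numeric(g)
    ad_acc(x, array(outer(gv, pv), dim = d))
    ad_acc(p, as.numeric(crossprod(xm, gv)))
  })
}

# H x W x C map <-> (H*W) x C token matrix (pixels in column-major order)
ad_tokens <- function(t, x) {
  d <- dim(x$value)
  ad_node(t, matrix(x$value, d[1] * d[2], d[3]),
          function(g) ad_acc(x, array(g, dim = d)))
}

ad_untokens <- function(t, x, h, w) {
  ad_node(t, array(x$value, dim = c(h, w, ncol(x$value))),
          function(g) ad_acc(x, matrix(g, h * w, ncol(x$value))))
}

# inverted dropout with an externally drawn keep mask
ad_dropout <- function(t, x, rate) {
  if (rate <= 0) return(x)
  keep <- array(stats::rbinom(length(x$value), 1L, 1 - rate) / (1 - rate),
                dim = dim(x$value))
  ad_node(t, x$value * keep, function(g) ad_acc(x, g * keep))
}

# A %*% t(B)
ad_matmul_nt <- function(t, a, b) {
  av <- a$value; bv <- b$value
  ad_node(t, tcrossprod(av, bv), function(g) {
    ad_acc(a, g %*% bv)
    ad_acc(b, crossprod(g, av))
  })
}

# column subset of a matrix node
ad_cols <- function(t, a, j) {
  av <- a$value
  ad_node(t, av[, j, drop = FALSE], function(g) {
    z <- av; z[] <- 0; z[, j] <- g
    ad_acc(a, z)
  })
}

ad_cbind <- function(t, lst) {
  if (length(lst) == 1L) return(lst[[1L]])
  ncols <- vapply(lst, function(n) ncol(n$value), 1L)
  ends <- cumsum(ncols)
  ad_node(t, do.call(cbind, lapply(lst, function(n) n$value)), function(g) {
    for (i in seq_along(lst))
      ad_acc(lst[[i]], g[, seq.int(ends[i] - ncols[i] + 1L, ends[i]),
                         drop = FALSE])
  })
}

# broadcast a length-C vector to an H x W x C map
ad_bcast_vec <- function(t, p, h, w) {
  n <- h * w
  ad_node(t, array(rep(p$value, each = n), dim = c(h, w, length(p$value))),
          function(g) ad_acc(p, as.numeric(colSums(matrix(g, n)))))
}

ad_reshape <- function(t, x, dims) {
  od <- dim(x$value)
  ad_node(t, array(x$value, dim = dims), function(g) {
    if (is.null(od)) ad_acc(x, as.numeric(g))
    else ad_acc(x, array(g, dim = od))
  })
}

# nearest-neighbor 2x upsampling
ad_upsample2n <- function(t, x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  ad_node(t, x$value[ri, ci, , drop = FALSE], function(g) {
    dd <- dim(g)
    m <- matrix(g, dd[1], dd[2] * dd[3])
    m <- m[seq(1, dd[1], 2), ] + m[seq(2, dd[1], 2), ]
    m <- array(m, dim = c(d[1], dd[2], dd[3]))
    m <- m[, seq(1, dd[2], 2), , drop = FALSE] +
         m[, seq(2, dd[2], 2), , drop = FALSE]
    ad_acc(x, m)
  })
}
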