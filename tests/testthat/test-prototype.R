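test_that("attention handles degenerate token sets and matches hand math", {
  set.seed(1)
  # single token: softmax of a scalar is 1, output is V
  v <- matrix(rnorm(3), 1)
  expect_equal(attention(matrix(rnorm(3), 1), matrix(rnorm(3), 1), v), v)
  # identical tokens: every output row is that token's V row
  q <- matrix(rep(c(1, -2), each = 4), 4)
  out <- attention(q, q, matrix(rep(c(0.5, 2), each = 4), 4))
  for (i in 1:4) expect_equal(out[i, ], c(0.5, 2))
  # explicit 3x2 case against the manual evaluation
  Q <- matrix(c(1, 0, -1, 2, 1, 0), 3); K <- matrix(c(0, 1, 1, 1, -1, 2), 3)
  V <- matrix(c(1, 2, 3, -1, 0, 1), 3)
  expect_equal(attention(Q, K, V, d = 2), oracle_attention(Q, K, V, 2),
               tolerance = 1e-12)
  expect_error(attention(Q, K[, 1, drop = FALSE], V), "conformable")
})

test_that("softmax rows of attention sum to one", {
  set.seed(2)
  for (k in 1:50) {
    n <- sample(2:5, 1)
    Q <- matrix(rnorm(n * 3, 0, 3), n)
    K <- matrix(rnorm(n * 3, 0, 3), n)
    sm <- attention(Q, K, diag(n))  # V = I returns the softmax matrix itself
    expect_equal(rowSums(sm), rep(1, n), tolerance = 1e-6)
    expect_true(all(sm >= 0))
  }
})

rand_tf_state <- function(d, ff = 2 * d) {
  list(wq = matrix(rnorm(d * d, 0, 0.5), d), wk = matrix(rnorm(d * d, 0, 0.5), d),
       wv = matrix(rnorm(d * d, 0, 0.5), d), wo = matrix(rnorm(d * d, 0, 0.5), d),
       "ff1.w" = matrix(rnorm(d * ff, 0, 0.5), d, ff), "ff1.b" = rnorm(ff),
       "ff2.w" = matrix(rnorm(ff * d, 0, 0.5), ff, d), "ff2.b" = rnorm(d),
       "ln1.g" = runif(d, 0.5, 1.5), "ln1.b" = rnorm(d, 0, 0.2),
       "ln2.g" = runif(d, 0.5, 1.5), "ln2.b" = rnorm(d, 0, 0.2))
}

test_that("transformer_block preserves shape and matches its composition", {
  set.seed(3)
  st <- rand_tf_state(2)
  x <- matrix(rnorm(4), 2)
  out <- transformer_block(x, st, n_heads = 1)
  expect_equal(dim(out), dim(x))
  # straight-line composition: MHA -> add+LN -> FFN -> add+LN
  ln <- function(m, g, b) {
    t(apply(m, 1, function(r) {
      g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6) + b
    }))
  }
  mha <- oracle_attention(x %*% st$wq, x %*% st$wk, x %*% st$wv, 2) %*% st$wo
  s1 <- ln(x + mha, st[["ln1.g"]], st[["ln1.b"]])
  ffn <- pmax(sweep(s1 %*% st[["ff1.w"]], 2, st[["ff1.b"]], "+"), 0)
  ffn <- sweep(ffn %*% st[["ff2.w"]], 2, st[["ff2.b"]], "+")
  want <- ln(s1 + ffn, st[["ln2.g"]], st[["ln2.b"]])
  expect_equal(out, want, tolerance = 1e-6)
  expect_error(transformer_block(matrix(rnorm(9), 3), rand_tf_state(3),
                                 n_heads = 2), "divisible")
})

test_that("layer normalisation inside the block is exact", {
  ns <- asNamespace("fsseg")
  set.seed(4)
  t <- ns$ad_tape()
  x <- ns$ad_const(t, matrix(rnorm(40, 3, 5), 5))
  out <- ns$ad_layernorm_rows(t, x, ns$ad_const(t, rep(1, 8)),
                              ns$ad_const(t, rep(0, 8)))$value
  expect_lt(max(abs(rowMeans(out))), 1e-5)
  expect_lt(max(abs(apply(out, 1, function(r) mean(r^2)) - 1)), 1e-4)
})

test_that("masked_prototype is a masked average with safe degeneracies", {
  set.seed(5)
  x <- rand_map(4, 4, 3)
  ones <- matrix(1, 4, 4)
  expect_equal(masked_prototype(x, ones), se_squeeze(x), tolerance = 1e-6)
  z <- masked_prototype(x, matrix(0, 4, 4))
  expect_true(all(is.finite(z)))
  expect_equal(z, numeric(3), tolerance = 1e-4)
  expect_error(masked_prototype(x, matrix(1, 3, 4)), "spatial")
  for (k in 1:50) {
    y <- rand_map(3, 5, 4)
    m <- matrix(rbinom(15, 1, 0.5), 3)
    expect_equal(masked_prototype(y, m), oracle_masked_prototype(y, m),
                 tolerance = 1e-10)
  }
})

test_that("masked_prototype is permutation-equivariant", {
  set.seed(6)
  for (k in 1:20) {
    x <- rand_map(4, 4, 3)
    m <- matrix(rbinom(16, 1, 0.5), 4)
    p <- masked_prototype(x, m)
    perm <- sample(16)
    xp <- array(matrix(x, 16, 3)[perm, ], c(4, 4, 3))
    mp <- matrix(as.numeric(m)[perm], 4)
    expect_equal(masked_prototype(xp, mp), p, tolerance = 1e-6)
  }
})

test_that("channel_attention gates the prototype and matches its equation", {
  set.seed(7)
  zero <- list(w1 = matrix(0, 2, 4), b1 = numeric(2),
               w2 = matrix(0, 4, 2), b2 = numeric(4))
  p <- rnorm(4)
  expect_equal(channel_attention(p, zero), 0.5 * p)
  expect_equal(channel_attention(numeric(4), rand_se_state(4)), numeric(4))
  for (k in 1:50) {
    st <- rand_se_state(4)
    q <- rnorm(4)
    expect_equal(channel_attention(q, st), oracle_channel_attention(q, st),
                 tolerance = 1e-10)
  }
})

test_that("fuse concatenates with the broadcast prototype (conv transcription)", {
  set.seed(8)
  C <- 3
  q <- rand_map(4, 4, C)
  p <- rnorm(C)
  st <- list(w = array(rnorm(2 * C * C, 0, 0.5), c(1, 1, 2 * C, C)),
             b = rnorm(C), "bn.g" = runif(C, 0.5, 1.5), "bn.b" = rnorm(C))
  out <- fuse(q, p, st)
  expect_equal(dim(out), c(4, 4, C))
  cat3 <- array(c(q, array(rep(p, each = 16), c(4, 4, C))), c(4, 4, 2 * C))
  want <- pmax(oracle_instnorm(oracle_conv2d(cat3, st$w, st$b),
                               st[["bn.g"]], st[["bn.b"]]), 0)
  expect_equal(out, want, tolerance = 1e-6)
  # zero weights with identity norm give a zero map
  st0 <- list(w = array(0, c(1, 1, 2 * C, C)), b = numeric(C),
              "bn.g" = rep(1, C), "bn.b" = numeric(C))
  expect_equal(fuse(q, p, st0), array(0, c(4, 4, C)))
  expect_error(fuse(q, rnorm(2), st), "channels")
})

test_that("similarity_map is the rescaled per-pixel cosine", {
  set.seed(9)
  p <- rnorm(3)
  par <- array(rep(2 * p, each = 16), c(4, 4, 3))
  expect_equal(similarity_map(par, p), matrix(1, 4, 4), tolerance = 1e-5)
  expect_equal(similarity_map(-par, p), matrix(0, 4, 4), tolerance = 1e-5)
  # degenerate zero pixel maps to neutral 0.5
  zval <- similarity_map(array(0, c(2, 2, 3)), p)
  expect_equal(zval, matrix(0.5, 2, 2), tolerance = 1e-4)
  for (k in 1:50) {
    x <- rand_map(3, 4, 5)
    pr <- rnorm(5)
    expect_equal(similarity_map(x, pr), oracle_similarity_map(x, pr),
                 tolerance = 1e-5)
  }
})

test_that("modulate is a broadcast elementwise product", {
  set.seed(10)
  x <- rand_map(3, 3, 2)
  expect_equal(modulate(x, matrix(1, 3, 3)), x)
  expect_equal(modulate(x, matrix(0, 3, 3)), 0 * x)
  s <- matrix(runif(9), 3)
  got <- modulate(x, s)
  for (c in 1:2) for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j, c], x[i, j, c] * s[i, j])
})

test_that("run_prototype_module returns bounded similarity and is symmetric", {
  m <- tiny_model(size = 16, base = 2, levels = 2, seed = 21)
  ep <- generate_episode(phantom_config(image_size = 16, seed = 13))
  fs <- encode(ep$support$image, m)$bottleneck
  fq <- encode(ep$query_image, m)$bottleneck
  out <- run_prototype_module(fs, ep$support$mask, fq, m)
  expect_true(all(out$similarity >= 0 & out$similarity <= 1))
  expect_equal(dim(out$f_mod), dim(fq))
  # identical support/query content keeps the construction symmetric
  same <- run_prototype_module(fs, ep$support$mask, fs, m)
  swapped <- run_prototype_module(fs, ep$support$mask, fs, m)
  expect_identical(same$similarity, swapped$similarity)
  expect_error(run_prototype_module(fs, ep$support$mask,
                                    array(0, c(8, 8, 5)), m), "channel")
})

test_that("similarity map stays in [0,1] under fuzzing and hits 1 at the prototype", {
  set.seed(11)
  for (k in 1:1000) {
    x <- rand_map(2, 2, 3, sd = runif(1, 0.01, 10))
    p <- rnorm(3, 0, runif(1, 0.01, 10))
    s <- similarity_map(x, p)
    expect_true(all(s >= 0 & s <= 1))
  }
  # pixel equal to the (normalised) prototype scores exactly 1
  p <- c(3, -1, 2)
  x <- rand_map(3, 3, 3)
  x[2, 2, ] <- p
  s <- similarity_map(x, p)
  expect_equal(s[2, 2], 1, tolerance = 1e-5)
})
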