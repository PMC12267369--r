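# Straight-line, dependency-free transcriptions of the model equations,
# written with explicit loops. They serve as independent references for the
# package implementation and are deliberately naive.

oracle_se_squeeze <- function(x) {
  d <- dim(x)
  z <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + x[i, j, c]
    z[c] <- s / (d[1] * d[2])
  }
  z
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_se_recalibrate <- function(x, st) {
  z <- oracle_se_squeeze(x)
  h <- pmax(as.numeric(st$w1 %*% z + st$b1), 0)
  s <- oracle_sigmoid(as.numeric(st$w2 %*% h + st$b2))
  out <- x
  d <- dim(x)
  for (c in seq_len(d[3])) out[, , c] <- s[c] * x[, , c]
  out
}

oracle_conv2d <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; co <- dim(w)[4]; pad <- (k - 1) / 2
  out <- array(0, c(d[1], d[2], co))
  for (o in seq_len(co)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- b[o]
    for (c in seq_len(d[3])) for (di in seq_len(k)) for (dj in seq_len(k)) {
      si <- i + di - 1 - pad; sj <- j + dj - 1 - pad
      if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2])
        acc <- acc + x[si, sj, c] * w[di, dj, c, o]
    }
    out[i, j, o] <- acc
  }
  out
}

oracle_instnorm <- function(x, g, b, eps = 1e-5) {
  d <- dim(x); out <- x
  for (c in seq_len(d[3])) {
    v <- x[, , c]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    out[, , c] <- g[c] * (v - mu) / sqrt(s2 + eps) + b[c]
  }
  out
}

# Residual block: ReLU( SE(BN(conv2(ReLU(BN(conv1(x)))))) + proj(x) )
oracle_residual_block <- function(x, st) {
  f1 <- oracle_instnorm(oracle_conv2d(x, st[["conv1.w"]], st[["conv1.b"]]),
                        st[["bn1.g"]], st[["bn1.b"]])
  f1 <- pmax(f1, 0)
  f2 <- oracle_instnorm(oracle_conv2d(f1, st[["conv2.w"]], st[["conv2.b"]]),
                        st[["bn2.g"]], st[["bn2.b"]])
  f2 <- oracle_se_recalibrate(f2, list(w1 = st[["se.w1"]], b1 = st[["se.b1"]],
                                       w2 = st[["se.w2"]], b2 = st[["se.b2"]]))
  skip <- if (is.null(st[["proj.w"]])) x
          else oracle_conv2d(x, st[["proj.w"]], st[["proj.b"]])
  pmax(f2 + skip, 0)
}

oracle_attention <- function(Q, K, V, d) {
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    sc <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(sc - max(sc))
    a <- e / sum(e)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

oracle_masked_prototype <- function(x, m, eps = 1e-6) {
  d <- dim(x)
  num <- numeric(d[3]); den <- eps
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    num <- num + m[i, j] * x[i, j, ]
    den <- den + m[i, j]
  }
  num / den
}

oracle_channel_attention <- function(p, st) {
  h <- pmax(as.numeric(st$w1 %*% p + st$b1), 0)
  oracle_sigmoid(as.numeric(st$w2 %*% h + st$b2)) * p
}

oracle_attention_gate <- function(x, g, st) {
  xt <- oracle_conv2d(x, st$wx, st$bx)
  gt <- oracle_conv2d(g, st$wg, st$bg)
  f <- pmax(xt + gt, 0)
  alpha <- oracle_sigmoid(oracle_conv2d(f, st$wpsi, st$bpsi))[, , 1]
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- alpha * x[, , c]
  list(out = out, alpha = alpha)
}

# per-pixel cosine against a prototype, rescaled to [0,1]
oracle_similarity_map <- function(x, p, eps = 1e-6) {
  d <- dim(x)
  out <- matrix(0, d[1], d[2])
  pn <- p / sqrt(sum(p^2) + eps)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- x[i, j, ]
    vn <- v / sqrt(sum(v^2) + eps)
    out[i, j] <- (sum(vn * pn) + 1) / 2
  }
  pmin(pmax(out, 0), 1)
}

oracle_bce <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  tot <- 0
  for (i in seq_along(p))
    tot <- tot + y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])
  -tot / length(p)
}

oracle_focal <- function(p, y, alpha, gamma, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  tot <- 0
  for (i in seq_along(p))
    tot <- tot + alpha * (1 - p[i])^gamma *
      (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  -tot / length(p)
}

oracle_tversky <- function(p, y, a, b, eps) {
  tp <- sum(p * y); fn <- sum((1 - p) * y); fp <- sum(p * (1 - y))
  1 - (tp + eps) / (tp + a * fn + b * fp + eps)
}

oracle_dice_loss <- function(p, y, eps = 1e-6) {
  1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

# 4-connected flood fill component count (for mask topology checks)
count_components <- function(mask) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] == 1 && !visited[i0, j0]) {
      n <- n + 1L
      stack <- list(c(i0, j0))
      visited[i0, j0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] == 1 &&
              !visited[q[1], q[2]]) {
            visited[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  n
}

# small random helpers shared across tests
rand_map <- function(h, w, c, sd = 1) array(stats::rnorm(h * w * c, 0, sd),
                                            c(h, w, c))

rand_se_state <- function(C, cr = max(1, C %/% 4)) {
  list(w1 = matrix(stats::rnorm(cr * C), cr, C), b1 = stats::rnorm(cr),
       w2 = matrix(stats::rnorm(C * cr), C, cr), b2 = stats::rnorm(C))
}

rand_resblock_state <- function(cin, cout) {
  se <- rand_se_state(cout)
  st <- list("conv1.w" = array(stats::rnorm(9 * cin * cout, 0, 0.4),
                               c(3, 3, cin, cout)),
             "conv1.b" = stats::rnorm(cout),
             "bn1.g" = stats::runif(cout, 0.5, 1.5),
             "bn1.b" = stats::rnorm(cout, 0, 0.3),
             "conv2.w" = array(stats::rnorm(9 * cout * cout, 0, 0.4),
                               c(3, 3, cout, cout)),
             "conv2.b" = stats::rnorm(cout),
             "bn2.g" = stats::runif(cout, 0.5, 1.5),
             "bn2.b" = stats::rnorm(cout, 0, 0.3),
             "se.w1" = se$w1, "se.b1" = se$b1,
             "se.w2" = se$w2, "se.b2" = se$b2)
  if (cin != cout) {
    st[["proj.w"]] <- array(stats::rnorm(cin * cout, 0, 0.5),
                            c(1, 1, cin, cout))
    st[["proj.b"]] <- stats::rnorm(cout)
  }
  st
}

rand_gate_state <- function(C, inter = max(1, C %/% 2)) {
  list(wx = array(stats::rnorm(C * inter, 0, 0.5), c(1, 1, C, inter)),
       bx = stats::rnorm(inter),
       wg = array(stats::rnorm(C * inter, 0, 0.5), c(1, 1, C, inter)),
       bg = stats::rnorm(inter),
       wpsi = array(stats::rnorm(inter, 0, 0.5), c(1, 1, inter, 1)),
       bpsi = stats::rnorm(1))
}

tiny_model <- function(size = 16, base = 2, levels = 2, tf = 1, heads = 1,
                       dropout = 0, seed = 11) {
  cfg <- model_config(image_size = size, base_width = base,
                      n_levels = levels, transformer_layers = tf,
                      n_heads = heads, dropout_rate = dropout)
  init_model(cfg, seed = seed)
}
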