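# Squeeze-and-excitation residual encoder. Support and query images pass
# through the same parameters (shared-weight branches); each level is one
# SE-residual block whose pre-pool output is kept as a skip feature, followed
# by non-overlapping 2x2 max pooling.

# SE recalibration on the tape: squeeze (GAP) -> two-layer excitation with
# sigmoid gate -> channel-wise rescaling.
se_ad <- function(t, x, P) {
  z <- ad_gap(t, x)
  h <- ad_relu(t, ad_matvec(t, P("se.w1"), z, P("se.b1")))
  s <- ad_sigmoid(t, ad_matvec(t, P("se.w2"), h, P("se.b2")))
  ad_chan_scale(t, x, s)
}

# residual block: ReLU( SE(BN(conv2(ReLU(BN(conv1(x)))))) + proj(x) )
resblock_ad <- function(t, x, P, mode, dropout_rate = 0) {
  f1 <- ad_relu(t, ad_instnorm(t, ad_conv2d(t, x, P("conv1.w"), P("conv1.b")),
                               P("bn1.g"), P("bn1.b")))
  f2 <- ad_instnorm(t, ad_conv2d(t, f1, P("conv2.w"), P("conv2.b")),
                    P("bn2.g"), P("bn2.b"))
  f2 <- se_ad(t, f2, P)
  skip <- if (is.null(P("proj.w"))) x
          else ad_conv2d(t, x, P("proj.w"), P("proj.b"))
  out <- ad_relu(t, ad_add(t, f2, skip))
  if (mode == "train" && dropout_rate > 0) out <- ad_dropout(t, out, dropout_rate)
  out
}

encode_ad <- function(t, image, P, config, mode = "eval") {
  v <- image$value
  if (is.matrix(v)) {
    img2d <- image
    image <- ad_node(t, array(v, dim = c(dim(v), 1L)),
                     function(g) ad_acc(img2d, g[, , 1]))
  }
  if (dim(image$value)[1] %% 2^config$n_levels != 0)
    stop("input size must be divisible by 2^n_levels")
  skips <- vector("list", config$n_levels)
  x <- image
  for (l in seq_len(config$n_levels)) {
    x <- resblock_ad(t, x, leaf_env(t, P, sprintf("enc.l%d", l)),
                     mode, config$dropout_rate)
    skips[[l]] <- x
    x <- ad_maxpool2(t, x)
  }
  list(bottleneck = x, skips = skips)
}

# getter over a prefixed subset of leaves (NULL when the name is absent)
leaf_env <- function(t, P, prefix) {
  function(nm) P(paste(prefix, nm, sep = "."))
}

# build leaves for an ad-hoc state list and return value(s) of an ad function
run_plain <- function(state, fn) {
  t <- ad_tape()
  L <- lapply(state, ad_const, tape = t)
  fn(t, leaf_at(L))
}

as_map3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' Squeeze: channel-wise spatial means
#'
#' Global average pooling of an `H x W x C` feature map into a length-C
#' vector of channel statistics.
#'
#' @param feature_map numeric `H x W x C` array.
#' @return numeric vector of length C.
#' @export
se_squeeze <- function(feature_map) {
  feature_map <- as_map3(feature_map)
  d <- dim(feature_map)
  if (d[1] < 1 || d[2] < 1) stop("empty spatial extent")
  as.numeric(colMeans(matrix(feature_map, d[1] * d[2], d[3])))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Computes the gate `s = sigmoid(W2 ReLU(W1 z + b1) + b2)` from the channel
#' statistics `z` of [se_squeeze()] and rescales every channel by its gate.
#'
#' @param feature_map numeric `H x W x C` array.
#' @param state list with `w1` (C/r x C), `b1`, `w2` (C x C/r), `b2`.
#' @return recalibrated array of the same shape.
#' @export
se_recalibrate <- function(feature_map, state) {
  feature_map <- as_map3(feature_map)
  if (ncol(state$w1) != dim(feature_map)[3])
    stop("channel count does not match SE state")
  st <- state[c("w1", "b1", "w2", "b2")]
  names(st) <- paste0("se.", names(st))
  run_plain(c(list(x = feature_map), st),
            function(t, P) se_ad(t, P("x"), P)$value)
}

#' SE-residual block
#'
#' `ReLU( SE(BN(conv2(ReLU(BN(conv1(x)))))) + proj(x) )` with 3x3 "same"
#' convolutions, per-episode batch normalisation, and an optional 1x1
#' projection on the skip path when channel counts differ. Spatial size is
#' preserved.
#'
#' @param feature_map numeric `H x W x C` array.
#' @param state named list of block parameters as produced inside
#'   [init_model()]: `conv1.w`, `conv1.b`, `bn1.g`, `bn1.b`, `conv2.w`,
#'   `conv2.b`, `bn2.g`, `bn2.b`, `se.w1`, `se.b1`, `se.w2`, `se.b2`, and
#'   optionally `proj.w`, `proj.b`.
#' @param mode `"train"` (applies dropout if `dropout_rate > 0`) or `"eval"`.
#' @param dropout_rate dropout probability in train mode.
#' @return array of the same spatial size.
#' @export
residual_block <- function(feature_map, state, mode = "eval",
                           dropout_rate = 0) {
  feature_map <- as_map3(feature_map)
  if (dim(state[["conv1.w"]])[3] != dim(feature_map)[3])
    stop("channel count does not match block state")
  run_plain(c(list(x = feature_map), state), function(t, P)
    resblock_ad(t, P("x"), P, mode, dropout_rate)$value)
}

#' Encode an image into a feature pyramid
#'
#' Runs the SE-residual encoder: at each level a residual block (its output
#' kept as the skip feature) followed by 2x2 max pooling. The bottleneck is
#' the deepest post-pool map. Identical weights process support and query
#' images.
#'
#' @param image `H x W` matrix (grayscale slice), `H` divisible by
#'   `2^n_levels`.
#' @param model an `fss_model` (or list with `params` and `config`).
#' @param mode `"train"` or `"eval"`.
#' @return list with `bottleneck` (`H' x W' x C` array) and `skips` (list of
#'   per-level arrays, shallowest first).
#' @export
encode <- function(image, model, mode = "eval") {
  t <- ad_tape()
  L <- ad_leaves(t, model$params)
  out <- encode_ad(t, ad_const(t, image), leaf_at(L), model$config, mode)
  list(bottleneck = out$bottleneck$value,
       skips = lapply(out$skips, function(n) n$value))
}
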