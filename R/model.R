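#' Model architecture configuration
#'
#' Encoder stage widths double per level starting at `base_width` (the
#' 64-to-512 doubling scheme at full scale); the bottleneck channel count is
#' `base_width * 2^(n_levels - 1)` and is also the transformer token
#' dimension. Defaults follow the best-validation architecture knobs: SE
#' reduction 16 (clamped so the bottleneck stays at least one unit wide),
#' dropout 0.3 after each residual block, a 2-layer single-head transformer
#' stack in the prototype module, bilinear upsampling in the decoder, and
#' one SE-residual refinement block per decoder level.
#'
#' @param image_size working resolution (square), divisible by `2^n_levels`.
#' @param base_width channels at the first encoder level.
#' @param n_levels number of residual-block + max-pool stages (>= 2).
#' @param se_reduction squeeze-and-excitation bottleneck ratio r.
#' @param dropout_rate dropout probability after residual blocks (train only).
#' @param transformer_layers depth of the prototype transformer stack.
#' @param n_heads attention heads (must divide the token dimension).
#' @param ffn_mult hidden width of the transformer FFN as a multiple of the
#'   token dimension.
#' @param upsample decoder upsampling: `"bilinear"` or `"nearest"`.
#' @param modulate_target which features the similarity map multiplies:
#'   `"fused"` (module-level description) or `"raw_query"`.
#' @param threshold probability cutoff for [binarize()].
#' @return an object of class `fss_config`.
#' @export
model_config <- function(image_size = 64L, base_width = 8L, n_levels = 3L,
                         se_reduction = 16L, dropout_rate = 0.3,
                         transformer_layers = 2L, n_heads = 1L,
                         ffn_mult = 2L, upsample = c("bilinear", "nearest"),
                         modulate_target = c("fused", "raw_query"),
                         threshold = 0.5) {
  upsample <- match.arg(upsample)
  modulate_target <- match.arg(modulate_target)
  if (base_width < 1) stop("base_width must be >= 1")
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (image_size %% 2^n_levels != 0)
    stop("image_size must be divisible by 2^n_levels")
  widths <- base_width * 2^(seq_len(n_levels) - 1L)
  d <- widths[n_levels]
  if (d %% n_heads != 0) stop("token dimension must be divisible by n_heads")
  structure(list(image_size = as.integer(image_size),
                 base_width = as.integer(base_width),
                 n_levels = as.integer(n_levels),
                 widths = as.integer(widths),
                 bottleneck_channels = as.integer(d),
                 se_reduction = as.integer(se_reduction),
                 dropout_rate = dropout_rate,
                 transformer_layers = as.integer(transformer_layers),
                 n_heads = as.integer(n_heads),
                 ffn_mult = as.integer(ffn_mult),
                 upsample = upsample,
                 modulate_target = modulate_target,
                 threshold = threshold),
            class = "fss_config")
}

## ---- parameter initialisation ---------------------------------------------

init_conv <- function(k, cin, cout, gain = 2) {
  w <- array(stats::rnorm(k * k * cin * cout, 0, sqrt(gain / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

init_lin <- function(nin, nout, gain = 2) {
  list(w = matrix(stats::rnorm(nout * nin, 0, sqrt(gain / nin)), nout, nin),
       b = numeric(nout))
}

# SE bottleneck width: C / r, clamped to at least 1
se_width <- function(c, r) max(1L, c %/% r)

init_se <- function(c, r) {
  cr <- se_width(c, r)
  fc1 <- init_lin(c, cr, gain = 2)
  fc2 <- init_lin(cr, c, gain = 1)
  list(w1 = fc1$w, b1 = fc1$b, w2 = fc2$w, b2 = fc2$b)
}

init_resblock <- function(cin, cout, r) {
  p <- list()
  c1 <- init_conv(3, cin, cout)
  c2 <- init_conv(3, cout, cout)
  p[["conv1.w"]] <- c1$w; p[["conv1.b"]] <- c1$b
  p[["bn1.g"]] <- rep(1, cout); p[["bn1.b"]] <- numeric(cout)
  p[["conv2.w"]] <- c2$w; p[["conv2.b"]] <- c2$b
  p[["bn2.g"]] <- rep(1, cout); p[["bn2.b"]] <- numeric(cout)
  se <- init_se(cout, r)
  p[["se.w1"]] <- se$w1; p[["se.b1"]] <- se$b1
  p[["se.w2"]] <- se$w2; p[["se.b2"]] <- se$b2
  if (cin != cout) {
    pr <- init_conv(1, cin, cout, gain = 1)
    p[["proj.w"]] <- pr$w; p[["proj.b"]] <- pr$b
  }
  p
}

prefix_names <- function(p, prefix) {
  names(p) <- paste(prefix, names(p), sep = ".")
  p
}

init_transformer_layer <- function(d, ffn_mult) {
  xav <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(1 / nin)),
                                    nin, nout)
  ff1 <- init_lin(d, ffn_mult * d)
  ff2 <- init_lin(ffn_mult * d, d, gain = 1)
  list("wq" = xav(d, d), "wk" = xav(d, d), "wv" = xav(d, d), "wo" = xav(d, d),
       "ff1.w" = t(ff1$w), "ff1.b" = ff1$b,
       "ff2.w" = t(ff2$w), "ff2.b" = ff2$b,
       "ln1.g" = rep(1, d), "ln1.b" = numeric(d),
       "ln2.g" = rep(1, d), "ln2.b" = numeric(d))
}

#' Initialise a full model
#'
#' Builds the flat named parameter list for the encoder, prototype module,
#' and decoder described by `config`. Convolutions use He initialisation;
#' transformer projections use Xavier; all normalisation affines start at
#' identity. The same parameters process support and query images (shared
#' weights).
#'
#' @param config an [model_config()] object.
#' @param seed integer seed for the initial weights.
#' @return an object of class `fss_model`: list with `params` (flat named
#'   list of numeric arrays) and `config`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fss_config"))
  with_seed(seed, {
    w <- config$widths
    L <- config$n_levels
    r <- config$se_reduction
    d <- config$bottleneck_channels
    p <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      p <- c(p, prefix_names(init_resblock(cin, w[l], r),
                             sprintf("enc.l%d", l)))
      cin <- w[l]
    }
    # prototype module (shared between support and query streams)
    se <- prefix_names(init_se(d, r), "proto.se")
    p <- c(p, se)
    for (k in seq_len(config$transformer_layers))
      p <- c(p, prefix_names(init_transformer_layer(d, config$ffn_mult),
                             sprintf("proto.tf%d", k)))
    attn <- init_se(d, r)  # same two-layer bottleneck shape as SE excitation
    p <- c(p, prefix_names(attn, "proto.attn"))
    fuse <- init_conv(1, 2L * d, d)
    p[["proto.fuse.w"]] <- fuse$w; p[["proto.fuse.b"]] <- fuse$b
    p[["proto.fuse.bn.g"]] <- rep(1, d); p[["proto.fuse.bn.b"]] <- numeric(d)
    # decoder, deepest level first at decode time
    for (l in seq_len(L)) {
      up_in <- if (l == L) w[L] else w[l + 1L]
      up <- init_conv(1, up_in, w[l], gain = 1)
      p[[sprintf("dec.l%d.up.w", l)]] <- up$w
      p[[sprintf("dec.l%d.up.b", l)]] <- up$b
      inter <- max(1L, w[l] %/% 2L)
      gx <- init_conv(1, w[l], inter, gain = 1)
      gg <- init_conv(1, w[l], inter, gain = 1)
      psi <- init_conv(1, inter, 1L, gain = 1)
      p[[sprintf("dec.l%d.gate.wx", l)]] <- gx$w
      p[[sprintf("dec.l%d.gate.bx", l)]] <- gx$b
      p[[sprintf("dec.l%d.gate.wg", l)]] <- gg$w
      p[[sprintf("dec.l%d.gate.bg", l)]] <- gg$b
      p[[sprintf("dec.l%d.gate.wpsi", l)]] <- psi$w
      p[[sprintf("dec.l%d.gate.bpsi", l)]] <- psi$b
      p <- c(p, prefix_names(init_resblock(2L * w[l], w[l], r),
                             sprintf("dec.l%d.ref", l)))
    }
    head <- init_conv(1, w[1], 1L, gain = 1)
    p[["head.w"]] <- head$w; p[["head.b"]] <- head$b
    structure(list(params = p, config = config), class = "fss_model")
  })
}

# getter factory over a named list of leaves, with optional prefix
leaf_at <- function(L, prefix = NULL) {
  if (is.null(prefix)) function(nm) L[[nm]]
  else function(nm) L[[paste(prefix, nm, sep = ".")]]
}

# nearest-neighbor downsampling of a binary mask to feature-map resolution
resize_mask_nearest <- function(mask, h, w) {
  ri <- pmin(pmax(floor((seq_len(h) - 0.5) / h * nrow(mask)) + 1L, 1L),
             nrow(mask))
  ci <- pmin(pmax(floor((seq_len(w) - 0.5) / w * ncol(mask)) + 1L, 1L),
             ncol(mask))
  mask[ri, ci, drop = FALSE]
}

# full forward pass on the tape; returns prediction and similarity nodes
forward_episode_ad <- function(t, P, episode, config, mode = "eval") {
  sup <- encode_ad(t, ad_const(t, episode$support$image), P, config, mode)
  qry <- encode_ad(t, ad_const(t, episode$query_image), P, config, mode)
  proto <- proto_ad(t, sup$bottleneck, episode$support$mask, qry$bottleneck,
                    P, config)
  pred <- decode_ad(t, proto$f_mod, qry$skips, P, config, mode)
  list(pred = pred, similarity = proto$similarity,
       prototype = proto$p_attn)
}

#' Segment a query image given one support pair
#'
#' Runs the full network in evaluation mode on one episode and returns the
#' probability map, the binarized mask, the prototype-similarity map, and
#' the attended prototype vector.
#'
#' @param model an [init_model()] object (or a trained checkpoint).
#' @param episode an `fss_episode` (support pair + query image).
#' @return list with `prob` (H x W in (0,1)), `mask` (binary H x W),
#'   `similarity` (H' x W' in `[0,1]`) and `prototype`.
#' @export
predict_episode <- function(model, episode) {
  t <- ad_tape()
  L <- ad_leaves(t, model$params)
  out <- forward_episode_ad(t, leaf_at(L), episode, model$config, "eval")
  prob <- out$pred$value[, , 1]
  list(prob = prob,
       mask = binarize(prob, model$config$threshold),
       similarity = out$similarity$value,
       prototype = out$prototype$value)
}

#' Save / load a model checkpoint
#'
#' Single-file RDS checkpoint with a format version tag and the full
#' architecture configuration echoed alongside the weights.
#'
#' @param model an `fss_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the `fss_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fss_model"))
  saveRDS(list(format = "fsseg-checkpoint-1", config = model$config,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fsseg-checkpoint-1"))
    stop("not a recognised checkpoint file")
  structure(list(params = x$params, config = x$config), class = "fss_model")
}
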