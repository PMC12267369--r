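# Attention-gated decoder: progressive 2x upsampling with a 1x1
# channel-halving convolution, attention-gated skip fusion (query-branch
# skips only), one SE-residual refinement block per level, and a sigmoid
# 1x1 head. The gating signal of each attention gate is the upsampled
# decoder feature at that level.

attention_gate_ad <- function(t, x, g, P) {
  xt <- ad_conv2d(t, x, P("wx"), P("bx"))
  gt <- ad_conv2d(t, g, P("wg"), P("bg"))
  f <- ad_relu(t, ad_add(t, xt, gt))
  alpha <- ad_sigmoid(t, ad_conv2d(t, f, P("wpsi"), P("bpsi")))
  alpha2d <- ad_reshape(t, alpha, dim(alpha$value)[1:2])
  list(out = ad_spat_scale(t, x, alpha2d), alpha = alpha2d)
}

decode_level_ad <- function(t, f_in, skip, P, config, mode) {
  up <- if (config$upsample == "bilinear") ad_upsample2(t, f_in)
        else ad_upsample2n(t, f_in)
  up <- ad_conv2d(t, up, P("up.w"), P("up.b"))
  gated <- attention_gate_ad(t, skip, up, leaf_env(t, P, "gate"))
  cat <- ad_concat_ch(t, gated$out, up)
  resblock_ad(t, cat, leaf_env(t, P, "ref"), mode, config$dropout_rate)
}

decode_ad <- function(t, f_mod, skips, P, config, mode = "eval") {
  x <- f_mod
  for (l in seq.int(config$n_levels, 1L))
    x <- decode_level_ad(t, x, skips[[l]],
                         leaf_env(t, P, sprintf("dec.l%d", l)), config, mode)
  ad_sigmoid(t, ad_conv2d(t, x, P("head.w"), P("head.b")))
}

#' Attention gate on a skip connection
#'
#' Projects the skip feature `x` and the gating signal `g` with 1x1
#' convolutions, fuses them additively through a ReLU, scores each pixel
#' with a 1x1 convolution + sigmoid (`alpha` in `(0,1)`), and rescales the
#' skip: `x_attn = alpha * x`.
#'
#' @param x skip feature map (`H x W x C`).
#' @param g gating feature map with the same spatial dimensions (upsampled
#'   decoder feature).
#' @param state list with `wx`, `bx`, `wg`, `bg` (1x1 projections to a
#'   shared intermediate width) and `wpsi`, `bpsi` (1x1 scorer).
#' @return list with `out` (gated skip) and `alpha` (`H x W` attention map).
#' @export
attention_gate <- function(x, g, state) {
  x <- as_map3(x); g <- as_map3(g)
  if (!all(dim(x)[1:2] == dim(g)[1:2]))
    stop("skip and gating signal have different spatial dimensions")
  run_plain(c(list(x = x, g = g), state), function(t, P) {
    res <- attention_gate_ad(t, P("x"), P("g"), P)
    list(out = res$out$value, alpha = res$alpha$value)
  })
}

#' One decoder level
#'
#' Upsamples the incoming feature map by 2 (bilinear by default), halves its
#' channels with a 1x1 convolution, gates the encoder skip with an attention
#' gate (gating signal = the upsampled feature), concatenates, and refines
#' with an SE-residual block. Output spatial dims equal the skip's.
#'
#' @param F_in deeper feature map (`H x W x C_in`).
#' @param skip encoder skip feature (`2H x 2W x C`).
#' @param state named list holding `up.w`, `up.b`, `gate.*` and `ref.*`
#'   parameters for this level (see [init_model()]).
#' @param config an [model_config()].
#' @param mode `"train"` or `"eval"`.
#' @return refined feature map (`2H x 2W x C`).
#' @export
decode_level <- function(F_in, skip, state, config, mode = "eval") {
  F_in <- as_map3(F_in); skip <- as_map3(skip)
  if (!all(dim(skip)[1:2] == 2L * dim(F_in)[1:2]))
    stop("skip spatial dims must be twice the input's")
  run_plain(c(list(f = F_in, s = skip), state), function(t, P)
    decode_level_ad(t, P("f"), P("s"), P, config, mode)$value)
}

#' Decode modulated features into a query probability mask
#'
#' Runs all decoder levels from the bottleneck up and applies the sigmoid
#' 1x1 head; every output value lies in (0,1) and the spatial dims equal the
#' query image's.
#'
#' @param F_mod modulated bottleneck features from the prototype module.
#' @param skips list of query-branch encoder skips (shallowest first).
#' @param model an `fss_model`.
#' @param mode `"train"` or `"eval"`.
#' @return `H x W` probability matrix.
#' @export
predict_mask <- function(F_mod, skips, model, mode = "eval") {
  if (length(skips) != model$config$n_levels)
    stop("pyramid depth does not match the configuration")
  t <- ad_tape()
  L <- ad_leaves(t, model$params)
  P <- leaf_at(L)
  out <- decode_ad(t, ad_const(t, as_map3(F_mod)),
                   lapply(skips, function(s) ad_const(t, as_map3(s))),
                   P, model$config, mode)
  out$value[, , 1]
}

#' Threshold a probability map into a binary mask
#'
#' @param prob numeric array with values in `[0,1]`.
#' @param threshold cutoff in `[0,1]`; pixels with `prob >= threshold`
#'   become 1.
#' @return binary array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- (prob >= threshold) * 1
  dim(out) <- dim(prob)
  out
}

#' Write a prediction to disk
#'
#' Binary mask as PNG, probability map as RDS, and a run-length encoding of
#' the mask (column-major) as JSON.
#'
#' @param prob probability matrix.
#' @param path_prefix output path without extension.
#' @param threshold binarization cutoff.
#' @return invisibly, the paths written.
#' @export
write_prediction <- function(prob, path_prefix, threshold = 0.5) {
  mask <- binarize(prob, threshold)
  png::writePNG(mask, paste0(path_prefix, "_mask.png"))
  saveRDS(prob, paste0(path_prefix, "_prob.rds"))
  r <- rle(as.integer(mask))
  jsonlite::write_json(list(shape = dim(mask), order = "column-major",
                            values = r$values, lengths = r$lengths),
                       paste0(path_prefix, "_rle.json"), auto_unbox = TRUE)
  invisible(paste0(path_prefix, c("_mask.png", "_prob.rds", "_rle.json")))
}
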