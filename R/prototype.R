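# Enhanced prototype module: SE + transformer refinement of both feature
# streams, masked average pooling of the support features into a prototype,
# channel attention, support-query fusion, cosine similarity, and feature
# modulation. The SE block and the transformer stack are shared between the
# support and query streams; the support stream is L2-normalised before its
# transformer stack (so the pooled prototype inherits normalised scale),
# the query stream after it, just before fusion.

attention_ad <- function(t, q, k, v, d_scale) {
  scores <- ad_mulc(t, ad_matmul_nt(t, q, k), 1 / sqrt(d_scale))
  ad_matmul(t, ad_softmax_rows(t, scores), v)
}

mha_ad <- function(t, x, P, n_heads) {
  d <- ncol(x$value)
  q <- ad_matmul(t, x, P("wq"))
  k <- ad_matmul(t, x, P("wk"))
  v <- ad_matmul(t, x, P("wv"))
  dh <- d %/% n_heads
  heads <- lapply(seq_len(n_heads), function(i) {
    idx <- seq.int((i - 1L) * dh + 1L, i * dh)
    attention_ad(t, ad_cols(t, q, idx), ad_cols(t, k, idx),
                 ad_cols(t, v, idx), dh)
  })
  ad_matmul(t, ad_cbind(t, heads), P("wo"))
}

# pre-norm-free block: LN(X + MHA(X)) then LN(step1 + FFN(step1))
transformer_block_ad <- function(t, x, P, n_heads) {
  x1 <- ad_layernorm_rows(t, ad_add(t, x, mha_ad(t, x, P, n_heads)),
                          P("ln1.g"), P("ln1.b"))
  ff <- ad_linear_rows(t, ad_relu(t, ad_linear_rows(t, x1, P("ff1.w"),
                                                    P("ff1.b"))),
                       P("ff2.w"), P("ff2.b"))
  ad_layernorm_rows(t, ad_add(t, x1, ff), P("ln2.g"), P("ln2.b"))
}

channel_attention_ad <- function(t, p, P) {
  h <- ad_relu(t, ad_matvec(t, P("w1"), p, P("b1")))
  gate <- ad_sigmoid(t, ad_matvec(t, P("w2"), h, P("b2")))
  ad_mul(t, gate, p)
}

transformer_stack_ad <- function(t, tokens, P, config) {
  for (k in seq_len(config$transformer_layers))
    tokens <- transformer_block_ad(t, tokens,
                                   leaf_env(t, P, sprintf("proto.tf%d", k)),
                                   config$n_heads)
  tokens
}

proto_ad <- function(t, f_s, m_s, f_q, P, config) {
  d <- dim(f_s$value)
  h <- d[1]; w <- d[2]
  pse <- leaf_env(t, P, "proto")   # se_ad reads "se.*" under this prefix
  # support stream: SE -> L2 normalise -> transformer -> masked pool -> attn
  s <- ad_l2norm_ch(t, se_ad(t, f_s, pse))
  s <- ad_untokens(t, transformer_stack_ad(t, ad_tokens(t, s), P, config),
                   h, w)
  m_small <- resize_mask_nearest(m_s, h, w)
  p_vec <- ad_masked_pool(t, s, m_small)
  p_attn <- channel_attention_ad(t, p_vec, leaf_env(t, P, "proto.attn"))
  # query stream: SE -> transformer -> L2 normalise -> fuse -> similarity
  q <- se_ad(t, f_q, pse)
  q <- ad_l2norm_ch(t, ad_untokens(t, transformer_stack_ad(t, ad_tokens(t, q),
                                                           P, config), h, w))
  pb <- ad_bcast_vec(t, p_vec, h, w)
  fused <- ad_relu(t, ad_instnorm(t,
    ad_conv2d(t, ad_concat_ch(t, q, pb), P("proto.fuse.w"),
              P("proto.fuse.b")),
    P("proto.fuse.bn.g"), P("proto.fuse.bn.b")))
  sim_raw <- ad_chan_dot(t, ad_l2norm_ch(t, fused), ad_l2norm_vec(t, p_attn))
  sim <- ad_clip(t, ad_mulc(t, ad_addc(t, sim_raw, 1), 0.5), 0, 1)
  target <- if (config$modulate_target == "fused") fused else f_q
  list(f_mod = ad_spat_scale(t, target, sim), similarity = sim,
       p_attn = p_attn, p_vec = p_vec, fused = fused)
}

## ---- plain-array operations ------------------------------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V`, rows of the softmax summing to one.
#'
#' @param Q,K,V token matrices; `Q` and `K` share the key dimension, `K` and
#'   `V` the token count.
#' @param d scaling dimension (defaults to the key dimension of `Q`).
#' @return matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
attention <- function(Q, K, V, d = ncol(Q)) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop("non-conformable attention inputs")
  run_plain(list(q = Q, k = K, v = V),
            function(t, P) attention_ad(t, P("q"), P("k"), P("v"), d)$value)
}

#' Transformer block (multi-head self-attention + FFN, post-norm)
#'
#' Computes multi-head self-attention of the tokens, adds it residually and
#' layer-normalises, then applies a two-layer ReLU feed-forward network with
#' a second residual + layer-norm step. Shape is preserved.
#'
#' @param tokens `N x d` token matrix.
#' @param state named list: `wq`, `wk`, `wv`, `wo` (`d x d`), `ff1.w`,
#'   `ff1.b`, `ff2.w`, `ff2.b`, `ln1.g`, `ln1.b`, `ln2.g`, `ln2.b`.
#' @param n_heads number of attention heads; must divide `d`.
#' @return refined `N x d` token matrix.
#' @export
transformer_block <- function(tokens, state, n_heads = 1L) {
  if (ncol(tokens) %% n_heads != 0)
    stop("token dimension not divisible by n_heads")
  run_plain(c(list(x = tokens), state), function(t, P)
    transformer_block_ad(t, P("x"), P, n_heads)$value)
}

#' Masked average pooling of support features into a prototype
#'
#' `P = sum_ij M(i,j) X(i,j,) / (sum_ij M(i,j) + eps)`: the spatial mean of
#' the feature vectors under the binary mask. An all-zero mask returns a
#' finite near-zero vector thanks to the epsilon guard.
#'
#' @param features `H x W x C` array (L2-normalised along channels upstream
#'   in the module pipeline).
#' @param mask binary `H x W` matrix at the same spatial resolution.
#' @param eps stabilising constant.
#' @return length-C prototype vector.
#' @export
masked_prototype <- function(features, mask, eps = 1e-6) {
  features <- as_map3(features)
  d <- dim(features)
  if (!all(dim(mask) == d[1:2]))
    stop("mask and features have different spatial dimensions")
  as.numeric(crossprod(matrix(features, d[1] * d[2], d[3]),
                       as.numeric(mask))) / (sum(mask) + eps)
}

#' Channel attention over a prototype vector
#'
#' `P_attn = sigmoid(W2 ReLU(W1 P + b1) + b2) * P`; the gate lies in
#' `(0,1)^C`.
#'
#' @param P length-C prototype vector.
#' @param state list with `w1`, `b1`, `w2`, `b2`.
#' @return attended prototype of length C.
#' @export
channel_attention <- function(P, state) {
  run_plain(c(list(p = P), state), function(t, Pn)
    channel_attention_ad(t, Pn("p"), Pn)$value)
}

#' Fuse refined query features with the broadcast support prototype
#'
#' Concatenates the query feature map with the prototype broadcast to every
#' pixel, then applies a 1x1 convolution, per-episode normalisation, and
#' ReLU. Output channels equal the query channels.
#'
#' @param query_map `H x W x C` refined query features.
#' @param P length-C prototype.
#' @param state list with `w` (`1 x 1 x 2C x C`), `b`, `bn.g`, `bn.b`.
#' @return fused `H x W x C` array.
#' @export
fuse <- function(query_map, P, state) {
  query_map <- as_map3(query_map)
  d <- dim(query_map)
  if (length(P) != d[3]) stop("prototype length must equal query channels")
  if (dim(state$w)[3] != 2L * d[3]) stop("fuse weights expect 2C channels")
  run_plain(c(list(q = query_map, p = P), state), function(t, Pn)
    ad_relu(t, ad_instnorm(t,
      ad_conv2d(t, ad_concat_ch(t, Pn("q"),
                                ad_bcast_vec(t, Pn("p"), d[1], d[2])),
                Pn("w"), Pn("b")),
      Pn("bn.g"), Pn("bn.b")))$value)
}

#' Cosine-similarity map between fused features and the attended prototype
#'
#' Both are L2-normalised along channels (epsilon-guarded: an all-zero
#' vector maps to raw similarity 0, i.e. scaled 0.5), the raw per-pixel
#' cosine in `[-1,1]` is rescaled by `(S+1)/2` and clipped to `[0,1]`.
#'
#' @param F_fused `H x W x C` array.
#' @param P_attn length-C attended prototype.
#' @return `H x W` matrix with values in `[0,1]`.
#' @export
similarity_map <- function(F_fused, P_attn) {
  F_fused <- as_map3(F_fused)
  run_plain(list(f = F_fused, p = P_attn), function(t, Pn) {
    raw <- ad_chan_dot(t, ad_l2norm_ch(t, Pn("f")),
                       ad_l2norm_vec(t, Pn("p")))
    ad_clip(t, ad_mulc(t, ad_addc(t, raw, 1), 0.5), 0, 1)$value
  })
}

#' Modulate features by the similarity map
#'
#' Per-pixel rescaling `F_mod(c,i,j) = F(c,i,j) * S(i,j)`; the similarity
#' map acts as a spatial attention mask.
#'
#' @param F_fused `H x W x C` array.
#' @param S `H x W` similarity map.
#' @return modulated array of the same shape.
#' @export
modulate <- function(F_fused, S) {
  F_fused <- as_map3(F_fused)
  F_fused * array(S, dim = dim(F_fused))
}

#' Run the full prototype module
#'
#' Support stream: SE recalibration, channel-wise L2 normalisation,
#' transformer stack, masked average pooling, channel attention. Query
#' stream: SE recalibration, transformer stack, L2 normalisation, fusion
#' with the broadcast prototype, cosine similarity to the attended
#' prototype, and similarity modulation.
#'
#' @param F_s,F_q support and query bottleneck features (`H' x W' x C`).
#' @param M_s binary support mask at image resolution (resized internally
#'   with nearest neighbor).
#' @param model an `fss_model` supplying parameters and configuration.
#' @return list with `f_mod` (decoder input), `similarity` (`[0,1]` map) and
#'   `p_attn` (attended prototype).
#' @export
run_prototype_module <- function(F_s, M_s, F_q, model) {
  if (dim(F_s)[3] != dim(F_q)[3])
    stop("support and query features must share the channel count")
  t <- ad_tape()
  L <- ad_leaves(t, model$params)
  out <- proto_ad(t, ad_const(t, F_s), M_s, ad_const(t, F_q),
                  leaf_at(L), model$config)
  list(f_mod = out$f_mod$value, similarity = out$similarity$value,
       p_attn = out$p_attn$value)
}
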