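# Composite segmentation loss: weighted Dice + Focal + Tversky + BCE on soft
# probabilities. The exported functions evaluate the same tape operations the
# training loop differentiates, so the loss used for reporting and the loss
# used for gradients cannot drift apart.

#' Weights of the combined loss
#'
#' Non-negative coefficients for Dice, Focal, Tversky, and BCE terms, summing
#' to one. The defaults (0.30, 0.25, 0.30, 0.15) are the best tuning-grid
#' configuration and are used throughout.
#'
#' @param alpha Dice weight.
#' @param beta Focal weight.
#' @param gamma Tversky weight.
#' @param delta BCE weight.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.30, beta = 0.25, gamma = 0.30,
                         delta = 0.15) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-6) stop("loss weights must sum to one")
  structure(as.list(w), class = "loss_weights")
}

#' Focal loss parameters
#'
#' @param alpha_f positive balance weight.
#' @param gamma_f focusing exponent (>= 0); 0 recovers plain cross-entropy.
#' @param symmetric if `FALSE` (default) the modulating factor is
#'   `alpha (1 - p)^gamma` applied to both the positive and negative terms;
#'   if `TRUE` the conventional symmetrised `p_t` form is used instead.
#' @return an object of class `focal_params`.
#' @export
focal_params <- function(alpha_f = 0.25, gamma_f = 2, symmetric = FALSE) {
  if (alpha_f <= 0) stop("alpha_f must be positive")
  if (gamma_f < 0) stop("gamma_f must be >= 0")
  structure(list(alpha_f = alpha_f, gamma_f = gamma_f,
                 symmetric = isTRUE(symmetric)), class = "focal_params")
}

#' Tversky loss parameters
#'
#' @param alpha_t false-negative penalty (>= 0).
#' @param beta_t false-positive penalty (>= 0).
#' @param epsilon stabilising constant (> 0). With `alpha_t = beta_t = 0.5`
#'   the Tversky loss equals the Dice loss.
#' @return an object of class `tversky_params`.
#' @export
tversky_params <- function(alpha_t = 0.7, beta_t = 0.3, epsilon = 1e-6) {
  if (alpha_t < 0 || beta_t < 0) stop("penalties must be >= 0")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(alpha_t = alpha_t, beta_t = beta_t, epsilon = epsilon),
            class = "tversky_params")
}

check_loss_inputs <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth have different shapes")
  if (!all(truth %in% c(0, 1))) stop("truth labels must be binary")
}

# y*log(p) + (1-y)*log(1-p) with probability clipping, as a tape node
ce_terms_ad <- function(t, pred, y, eps = 1e-7) {
  p <- ad_clip(t, pred, eps, 1 - eps)
  lp <- ad_log(t, p)
  lq <- ad_log(t, ad_addc(t, ad_neg(t, p), 1))
  list(p = p, term = ad_add(t, ad_mulc(t, lp, y), ad_mulc(t, lq, 1 - y)))
}

bce_ad <- function(t, pred, y) {
  ad_neg(t, ad_mean(t, ce_terms_ad(t, pred, y)$term))
}

focal_ad <- function(t, pred, y, fp) {
  ce <- ce_terms_ad(t, pred, y)
  if (fp$symmetric) {
    pt <- ad_add(t, ad_mulc(t, ce$p, y),
                 ad_mulc(t, ad_addc(t, ad_neg(t, ce$p), 1), 1 - y))
    mod <- ad_powc(t, ad_addc(t, ad_neg(t, pt), 1), fp$gamma_f)
    term <- ad_mul(t, mod, ad_log(t, pt))
  } else {
    mod <- ad_powc(t, ad_addc(t, ad_neg(t, ce$p), 1), fp$gamma_f)
    term <- ad_mul(t, mod, ce$term)
  }
  ad_neg(t, ad_mulc(t, ad_mean(t, term), fp$alpha_f))
}

tversky_ad <- function(t, pred, y, tp_par) {
  tp <- ad_sum(t, ad_mulc(t, pred, y))
  fn <- ad_sum(t, ad_mulc(t, ad_addc(t, ad_neg(t, pred), 1), y))
  fp <- ad_sum(t, ad_mulc(t, pred, 1 - y))
  num <- ad_addc(t, tp, tp_par$epsilon)
  den <- ad_addc(t, ad_add(t, tp, ad_add(t, ad_mulc(t, fn, tp_par$alpha_t),
                                         ad_mulc(t, fp, tp_par$beta_t))),
                 tp_par$epsilon)
  ad_addc(t, ad_neg(t, ad_div(t, num, den)), 1)
}

dice_loss_ad <- function(t, pred, y, eps = 1e-6) {
  inter <- ad_sum(t, ad_mulc(t, pred, y))
  num <- ad_addc(t, ad_mulc(t, inter, 2), eps)
  den <- ad_addc(t, ad_addc(t, ad_sum(t, pred), sum(y)), eps)
  ad_addc(t, ad_neg(t, ad_div(t, num, den)), 1)
}

combined_ad <- function(t, pred, y, w, fp, tp) {
  parts <- list(dice = dice_loss_ad(t, pred, y),
                focal = focal_ad(t, pred, y, fp),
                tversky = tversky_ad(t, pred, y, tp),
                bce = bce_ad(t, pred, y))
  total <- ad_add(t, ad_add(t, ad_mulc(t, parts$dice, w$alpha),
                            ad_mulc(t, parts$focal, w$beta)),
                  ad_add(t, ad_mulc(t, parts$tversky, w$gamma),
                         ad_mulc(t, parts$bce, w$delta)))
  list(total = total,
       components = vapply(parts, function(n) n$value, numeric(1)))
}

loss_value <- function(pred, truth, fn) {
  check_loss_inputs(pred, truth)
  t <- ad_tape()
  fn(t, ad_const(t, pred))$value
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum( y log p + (1-y) log(1-p) )` on soft probabilities, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred numeric array of predicted probabilities.
#' @param truth binary array of the same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, truth) {
  loss_value(pred, truth, function(t, p) bce_ad(t, p, truth))
}

#' Focal loss
#'
#' `-(1/N) sum( alpha (1-p)^gamma [ y log p + (1-y) log(1-p) ] )`: cross-
#' entropy rescaled by a modulating factor that down-weights well-classified
#' foreground pixels. With `alpha_f = 1, gamma_f = 0` it equals [bce_loss()].
#'
#' @inheritParams bce_loss
#' @param params a [focal_params()] object.
#' @return non-negative scalar.
#' @export
focal_loss <- function(pred, truth, params = focal_params()) {
  loss_value(pred, truth, function(t, p) focal_ad(t, p, truth, params))
}

#' Tversky loss
#'
#' `1 - (TP + eps) / (TP + alpha FN + beta FP + eps)` on soft counts
#' `TP = sum(p y)`, `FN = sum((1-p) y)`, `FP = sum(p (1-y))`. Generalises the
#' Dice loss, which it equals at `alpha_t = beta_t = 0.5`.
#'
#' @inheritParams bce_loss
#' @param params a [tversky_params()] object.
#' @return scalar in `[0, 1]`.
#' @export
tversky_loss <- function(pred, truth, params = tversky_params()) {
  loss_value(pred, truth, function(t, p) tversky_ad(t, p, truth, params))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p y) + eps) / (sum(p) + sum(y) + eps)`.
#'
#' @inheritParams bce_loss
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth) {
  loss_value(pred, truth, function(t, p) dice_loss_ad(t, p, truth))
}

#' Combined segmentation loss
#'
#' `alpha L_Dice + beta L_Focal + gamma L_Tversky + delta L_BCE` with the
#' per-component values returned for logging.
#'
#' @inheritParams bce_loss
#' @param weights a [loss_weights()] object.
#' @param focal a [focal_params()] object.
#' @param tversky a [tversky_params()] object.
#' @return list with `total` (scalar) and `components` (named numeric vector
#'   `dice`, `focal`, `tversky`, `bce`).
#' @export
combined_loss <- function(pred, truth, weights = loss_weights(),
                          focal = focal_params(),
                          tversky = tversky_params()) {
  stopifnot(inherits(weights, "loss_weights"))
  check_loss_inputs(pred, truth)
  t <- ad_tape()
  res <- combined_ad(t, ad_const(t, pred), truth, weights, focal, tversky)
  list(total = res$total$value, components = res$components)
}
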