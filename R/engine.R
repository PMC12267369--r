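# Episodic 1-shot training engine: Adam with a fixed learning rate of 0.001,
# global gradient-norm clipping at 1.0, a batch of one episode per step, and
# frozen-weight evaluation over held-out episode streams.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (fixed).
#' @param clip_norm global gradient-norm clip.
#' @param epochs number of epochs.
#' @param episodes_per_epoch training episodes per epoch (phantom streams
#'   have no natural epoch length, so it is explicit).
#' @param val_episodes held-out episodes scored after each epoch.
#' @param weights,focal,tversky loss configuration objects.
#' @param seed master seed for weight init order, dropout, and episode
#'   streams.
#' @param checkpoint_path optional path; the best-validation-Dice model is
#'   saved there after each validation pass, enabling resumption.
#' @param log_path optional JSON-lines step log path.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, clip_norm = 1.0,
                         epochs = 1L, episodes_per_epoch = 100L,
                         val_episodes = 20L,
                         weights = loss_weights(), focal = focal_params(),
                         tversky = tversky_params(), seed = 1L,
                         checkpoint_path = NULL, log_path = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (clip_norm <= 0) stop("clip_norm must be positive")
  structure(list(learning_rate = learning_rate, clip_norm = clip_norm,
                 epochs = as.integer(epochs),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 val_episodes = as.integer(val_episodes),
                 weights = weights, focal = focal, tversky = tversky,
                 seed = as.integer(seed), checkpoint_path = checkpoint_path,
                 log_path = log_path),
            class = "train_config")
}

#' Turn an episode source into a deterministic episode stream
#'
#' A source is either a [phantom_config()] (episodes are synthesised), a
#' list of `slice_pair` objects (support/query slices are sampled from it:
#' the support must have a non-empty mask and the query is always a
#' different slice), or an existing stream closure (returned as is).
#'
#' @param source a `phantom_config`, a list of `slice_pair`s, or a function.
#' @param seed stream seed (overrides the seed inside a `phantom_config`).
#' @return a function of no arguments returning the next `fss_episode`.
#' @export
episode_stream <- function(source, seed = 1L) {
  if (is.function(source)) return(source)
  if (inherits(source, "phantom_config")) {
    source$seed <- as.integer(seed)
    return(phantom_stream(source))
  }
  if (is.list(source) && length(source) &&
      all(vapply(source, inherits, TRUE, "slice_pair"))) {
    eligible <- which(vapply(source, function(s) sum(s$mask) > 0, TRUE))
    if (!length(eligible) || length(source) < 2L)
      stop("exhausted source: no eligible support/query split",
           call. = FALSE)
    i <- 0L
    return(function() {
      i <<- i + 1L
      with_seed(seed + i, {
        s <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        q <- sample(setdiff(seq_along(source), s), 1L)
        structure(list(support = source[[s]],
                       query_image = source[[q]]$image,
                       query_mask = source[[q]]$mask),
                  class = "fss_episode")
      })
    })
  }
  stop("invalid episode source", call. = FALSE)
}

#' Draw the next episode from a stream
#'
#' @param stream a stream from [episode_stream()].
#' @return an `fss_episode`.
#' @export
sample_episode <- function(stream) {
  if (!is.function(stream)) stop("invalid episode source", call. = FALSE)
  stream()
}

#' Initialise optimiser state for a model
#'
#' @param model an `fss_model`.
#' @return an object of class `fss_train_state` holding the model plus Adam
#'   first/second moment estimates and the step counter.
#' @export
train_state <- function(model) {
  zeros <- lapply(model$params, function(p) { p[] <- 0; p })
  structure(list(model = model, m = zeros, v = zeros, step = 0L),
            class = "fss_train_state")
}

global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

#' One episodic training step
#'
#' Forward pass (encode support and query, prototype module, decode),
#' combined loss, backward pass, global gradient-norm clipping, and an Adam
#' update. The batch is one episode.
#'
#' @param state an `fss_train_state`.
#' @param episode an `fss_episode` (already preprocessed / at working
#'   resolution).
#' @param config a [train_config()].
#' @return list with `state` (updated) and `record` (step, total and
#'   per-component loss, pre/post-clip gradient norms).
#' @export
train_step <- function(state, episode, config = train_config()) {
  stopifnot(inherits(state, "fss_train_state"))
  model <- state$model
  t <- ad_tape()
  L <- ad_leaves(t, model$params)
  out <- forward_episode_ad(t, leaf_at(L), episode, model$config, "train")
  pred2d <- ad_reshape(t, out$pred, dim(out$pred$value)[1:2])
  loss <- combined_ad(t, pred2d, episode$query_mask, config$weights,
                      config$focal, config$tversky)
  if (!is.finite(loss$total$value))
    stop(sprintf("non-finite loss at step %d (components: %s)",
                 state$step + 1L,
                 paste(sprintf("%s=%.4g", names(loss$components),
                               loss$components), collapse = ", ")))
  ad_backward(t, loss$total)
  grads <- ad_grads(L)
  gn <- global_norm(grads)
  scale <- if (gn > config$clip_norm) config$clip_norm / gn else 1
  if (scale < 1) grads <- lapply(grads, function(g) g * scale)
  state$step <- state$step + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  c1 <- 1 - b1^state$step
  c2 <- 1 - b2^state$step
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    model$params[[nm]] <- model$params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  state$model <- model
  list(state = state,
       record = c(list(step = state$step, loss = loss$total$value,
                       grad_norm_raw = gn,
                       grad_norm = global_norm(grads)),
                  as.list(loss$components)))
}

params_checksum <- function(params) {
  sum(vapply(params, function(p) sum(p) + sum(p * p), numeric(1)))
}

#' Frozen-weight evaluation over an episode stream
#'
#' Scores `n_episodes` episodes with binarized predictions; no parameter is
#' updated (verified internally by checksum). For plumbing tests, `model`
#' may also be a function `episode -> probability matrix`.
#'
#' @param model an `fss_model`, or a predictor function.
#' @param source an episode source (see [episode_stream()]).
#' @param n_episodes number of episodes to score (>= 1).
#' @param seed stream seed.
#' @param threshold binarization cutoff (defaults to the model's).
#' @return a `metric_report`.
#' @export
evaluate <- function(model, source, n_episodes = 50L, seed = 1L,
                     threshold = NULL) {
  if (n_episodes < 1) stop("n_episodes must be >= 1")
  stream <- episode_stream(source, seed)
  predictor <- if (is.function(model)) {
    model
  } else {
    before <- params_checksum(model$params)
    if (is.null(threshold)) threshold <- model$config$threshold
    function(ep) predict_episode(model, ep)$prob
  }
  if (is.null(threshold)) threshold <- 0.5
  recs <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    ep <- sample_episode(stream)
    pm <- binarize(predictor(ep), threshold)
    recs[[i]] <- list(episode = i,
                      dice = dice_coefficient(pm, ep$query_mask),
                      iou = iou(pm, ep$query_mask),
                      specificity = specificity(pm, ep$query_mask))
  }
  if (!is.function(model) &&
      !identical(before, params_checksum(model$params)))
    stop("evaluation must not modify parameters")
  aggregate_metrics(recs)
}

#' Fit a model with episodic 1-shot training
#'
#' Runs `epochs * episodes_per_epoch` training steps, validating after each
#' epoch on a held-out stream and keeping the best-validation-Dice
#' parameters. Fully deterministic for a fixed `(config, sources, seed)`
#' when the sources are configs rather than live closures.
#'
#' @param model an `fss_model` to train.
#' @param config a [train_config()].
#' @param train_source,val_source episode sources (see [episode_stream()]);
#'   validation defaults to the training source with a shifted stream seed.
#' @return list with `model` (best validation Dice), `final` (last-step
#'   model), `best_val_dice`, and `log` (list of per-step records and
#'   per-epoch validation summaries).
#' @export
fit <- function(model, config = train_config(), train_source,
                val_source = train_source) {
  stopifnot(inherits(model, "fss_model"), inherits(config, "train_config"))
  set.seed(config$seed)          # dropout and any in-step randomness
  stream <- episode_stream(train_source, seed = config$seed)
  state <- train_state(model)
  steps <- list()
  epochs_log <- list()
  best <- model
  best_dice <- -Inf
  logcon <- if (!is.null(config$log_path)) file(config$log_path, "w")
  on.exit(if (!is.null(logcon)) close(logcon))
  for (e in seq_len(config$epochs)) {
    for (i in seq_len(config$episodes_per_epoch)) {
      ep <- sample_episode(stream)
      res <- train_step(state, ep, config)
      state <- res$state
      steps[[length(steps) + 1L]] <- res$record
      if (!is.null(logcon))
        writeLines(jsonlite::toJSON(res$record, auto_unbox = TRUE), logcon)
    }
    val <- evaluate(state$model, val_source, config$val_episodes,
                    seed = config$seed + 100003L)
    epochs_log[[e]] <- list(epoch = e, val_dice = val$mean[["dice"]],
                            val_iou = val$mean[["iou"]],
                            val_specificity = val$mean[["specificity"]])
    if (val$mean[["dice"]] > best_dice) {
      best_dice <- val$mean[["dice"]]
      best <- state$model
      if (!is.null(config$checkpoint_path))
        save_checkpoint(best, config$checkpoint_path)
    }
  }
  list(model = best, final = state$model, best_val_dice = best_dice,
       log = list(steps = steps, epochs = epochs_log))
}
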