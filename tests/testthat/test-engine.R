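test_that("episode streams are deterministic and reject invalid sources", {
  pc <- phantom_config(image_size = 16, seed = 3)
  s1 <- episode_stream(pc, seed = 5)
  s2 <- episode_stream(pc, seed = 5)
  for (k in 1:5) expect_identical(sample_episode(s1), sample_episode(s2))
  expect_error(episode_stream(42), "invalid episode source")
  expect_error(sample_episode("nope"), "invalid episode source")
})

test_that("slice-pair sources never pair a slice with itself and need foreground", {
  set.seed(1)
  pairs <- lapply(1:6, function(i) {
    generate_slice(phantom_config(image_size = 16, seed = i,
                                  n_blobs = (i %% 2)))
  })
  stream <- episode_stream(pairs, seed = 2)
  for (k in 1:200) {
    ep <- sample_episode(stream)
    expect_gt(sum(ep$support$mask), 0)
    expect_false(identical(ep$support$image, ep$query_image))
  }
  empty <- lapply(1:3, function(i)
    generate_slice(phantom_config(image_size = 16, n_blobs = 0, seed = i)))
  expect_error(episode_stream(empty), "exhausted")
})

test_that("train_step clips gradients and zero learning rate freezes weights", {
  m <- tiny_model(size = 16, base = 2, levels = 2, dropout = 0)
  ep <- generate_episode(phantom_config(image_size = 16, seed = 3))
  st <- train_state(m)
  cfg <- train_config(clip_norm = 0.05)   # low clip so clipping engages
  r <- train_step(st, ep, cfg)
  expect_lte(r$record$grad_norm, 0.05 + 1e-6)
  expect_gt(r$record$grad_norm_raw, r$record$grad_norm)
  tiny_lr <- train_config(learning_rate = 1e-12)
  r2 <- train_step(train_state(m), ep, tiny_lr)
  for (nm in names(m$params))
    expect_equal(r2$state$model$params[[nm]], m$params[[nm]],
                 tolerance = 1e-6)
})

test_that("repeated steps on one episode drive the loss down", {
  m <- tiny_model(size = 32, base = 4, levels = 2, dropout = 0)
  ep <- generate_episode(phantom_config(image_size = 32, seed = 4))
  st <- train_state(m)
  cfg <- train_config()
  set.seed(5)
  first <- NA; last <- NA
  for (i in 1:100) {
    r <- train_step(st, ep, cfg)
    st <- r$state
    if (i == 1) first <- r$record$loss
    last <- r$record$loss
  }
  expect_lt(last, 0.7 * first)
})

test_that("evaluation freezes parameters and scores a perfect oracle at 1", {
  m <- tiny_model(size = 16, base = 2, levels = 2)
  pc <- phantom_config(image_size = 16, seed = 9)
  before <- m$params
  rep <- evaluate(m, pc, n_episodes = 5, seed = 1)
  expect_identical(m$params, before)
  expect_s3_class(rep, "metric_report")
  expect_true(all(unlist(rep$mean) >= 0 & unlist(rep$mean) <= 1))
  expect_identical(rep$n_episodes, 5L)
  # deterministic: same seed, same report
  expect_equal(evaluate(m, pc, n_episodes = 5, seed = 1), rep)
  # an oracle predictor that returns the query mask scores perfectly
  oracle <- function(ep) ep$query_mask
  perfect <- evaluate(oracle, pc, n_episodes = 5, seed = 1)
  expect_equal(unname(perfect$mean[c("dice", "iou")]), c(1, 1))
  expect_error(evaluate(m, pc, n_episodes = 0), "n_episodes")
})

test_that("fit honours epochs = 0 and logs steps as JSON lines", {
  m <- tiny_model(size = 16, base = 2, levels = 2)
  pc <- phantom_config(image_size = 16, seed = 2)
  res0 <- fit(m, train_config(epochs = 0), pc)
  expect_identical(res0$model$params, m$params)
  expect_length(res0$log$steps, 0)
  dir <- withr::local_tempdir()
  lp <- file.path(dir, "steps.jsonl")
  ckpt <- file.path(dir, "best.ckpt")
  res <- fit(m, train_config(epochs = 1, episodes_per_epoch = 3,
                             val_episodes = 2, seed = 4, log_path = lp,
                             checkpoint_path = ckpt), pc)
  lines <- readLines(lp)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[2])
  expect_identical(rec$step, 2L)
  expect_true(is.finite(rec$loss))
  expect_true(file.exists(ckpt))
  back <- load_checkpoint(ckpt)
  expect_equal(back$params, res$model$params)
})

test_that("fit is reproducible end to end for a fixed seed", {
  m <- tiny_model(size = 16, base = 2, levels = 2, dropout = 0.3)
  pc <- phantom_config(image_size = 16, seed = 6)
  cfg <- train_config(epochs = 1, episodes_per_epoch = 4, val_episodes = 2,
                      seed = 11)
  r1 <- fit(m, cfg, pc)
  r2 <- fit(m, cfg, pc)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$log, r2$log)
})

test_that("checkpoints round-trip and reject foreign files", {
  m <- tiny_model(size = 16, base = 2, levels = 2)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.ckpt")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_equal(back$params, m$params)
  expect_equal(back$config, m$config)
  other <- file.path(dir, "x.rds")
  saveRDS(list(a = 1), other)
  expect_error(load_checkpoint(other), "checkpoint")
})

test_that("YAML run configs populate every section", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("model:", "  image_size: 32", "  base_width: 4",
               "  n_levels: 2", "preprocess:", "  target_size: 32",
               "loss:", "  alpha: 0.25", "  beta: 0.25", "  gamma: 0.25",
               "  delta: 0.25", "  focal:", "    gamma_f: 3",
               "train:", "  epochs: 2", "  episodes_per_epoch: 7",
               "phantom:", "  image_size: 32", "  seed: 5"), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$model$image_size, 32L)
  expect_equal(cfg$train$epochs, 2L)
  expect_equal(cfg$train$weights$alpha, 0.25)
  expect_equal(cfg$train$focal$gamma_f, 3)
  expect_equal(cfg$phantom$seed, 5L)
  expect_equal(cfg$preprocess$target_size, 32L)
})
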