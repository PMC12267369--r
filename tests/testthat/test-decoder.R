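test_that("attention_gate matches the equation chain and its edge cases", {
  set.seed(1)
  C <- 3
  x <- rand_map(4, 4, C)
  g <- rand_map(4, 4, C)
  st <- rand_gate_state(C)
  # zero scorer: alpha = 0.5 everywhere
  st0 <- st
  st0$wpsi[] <- 0; st0$bpsi[] <- 0
  r0 <- attention_gate(x, g, st0)
  expect_equal(r0$alpha, matrix(0.5, 4, 4))
  expect_equal(r0$out, 0.5 * x)
  # zero skip stays zero
  expect_equal(attention_gate(0 * x, g, st)$out, 0 * x)
  # random cases against the transcription oracle
  for (k in 1:50) {
    xs <- rand_map(3, 3, C); gs <- rand_map(3, 3, C)
    sts <- rand_gate_state(C)
    got <- attention_gate(xs, gs, sts)
    want <- oracle_attention_gate(xs, gs, sts)
    expect_equal(got$out, want$out, tolerance = 1e-6)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-6)
  }
  expect_error(attention_gate(x, rand_map(3, 3, C), st), "spatial")
})

test_that("gate coefficients are strictly inside (0,1) under fuzzing", {
  set.seed(2)
  for (k in 1:1000) {
    st <- rand_gate_state(2)
    a <- attention_gate(rand_map(2, 2, 2, sd = 3),
                        rand_map(2, 2, 2, sd = 3), st)$alpha
    expect_true(all(a > 0 & a < 1))
  }
})

test_that("decode_level upsamples, gates, and refines with correct shapes", {
  m <- tiny_model(size = 16, base = 2, levels = 2, seed = 5)
  st <- m$params[grep("^dec\\.l2\\.", names(m$params))]
  names(st) <- sub("^dec\\.l2\\.", "", names(st))
  f_in <- rand_map(4, 4, 4)   # deepest feature (w2 = 4 channels)
  skip <- rand_map(8, 8, 4)
  out <- decode_level(f_in, skip, st, m$config)
  expect_equal(dim(out), c(8, 8, 4))
  expect_error(decode_level(f_in, rand_map(16, 16, 4), st, m$config),
               "twice")
  # upsampling a constant map stays constant
  ns <- asNamespace("fsseg")
  expect_equal(ns$.cpp_upsample2_fw(array(2.5, c(3, 3, 2))),
               array(2.5, c(6, 6, 2)))
  # stage-by-stage composition: upsample -> 1x1 conv -> gate -> concat -> block
  up <- ns$.cpp_conv2d_fw(ns$.cpp_upsample2_fw(f_in), st[["up.w"]],
                          st[["up.b"]])
  gate <- oracle_attention_gate(skip, up,
                                list(wx = st[["gate.wx"]], bx = st[["gate.bx"]],
                                     wg = st[["gate.wg"]], bg = st[["gate.bg"]],
                                     wpsi = st[["gate.wpsi"]],
                                     bpsi = st[["gate.bpsi"]]))
  cat3 <- array(c(gate$out, up), c(8, 8, 8))
  ref <- st[grep("^ref\\.", names(st))]
  names(ref) <- sub("^ref\\.", "", names(ref))
  want <- oracle_residual_block(cat3, ref)
  expect_equal(out, want, tolerance = 1e-5)
})

test_that("predict_mask produces a full-resolution probability map", {
  m <- tiny_model(size = 16, base = 2, levels = 2, seed = 6)
  ep <- generate_episode(phantom_config(image_size = 16, seed = 2))
  enc_q <- encode(ep$query_image, m)
  enc_s <- encode(ep$support$image, m)
  pm <- run_prototype_module(enc_s$bottleneck, ep$support$mask,
                             enc_q$bottleneck, m)
  prob <- predict_mask(pm$f_mod, enc_q$skips, m)
  expect_equal(dim(prob), dim(ep$query_image))
  expect_true(all(prob > 0 & prob < 1))
  expect_error(predict_mask(pm$f_mod, enc_q$skips[1], m), "depth")
})

test_that("binarize thresholds with a >= convention", {
  expect_error(binarize(matrix(0.5, 2, 2), 1.5), "threshold")
  expect_equal(binarize(matrix(0.5, 2, 2), 0.5), matrix(1, 2, 2))
  expect_equal(binarize(matrix(runif(9), 3), 0), matrix(1, 3, 3))
  set.seed(3)
  p <- matrix(runif(25), 5)
  got <- binarize(p, 0.3)
  for (i in 1:5) for (j in 1:5)
    expect_identical(got[i, j], as.numeric(p[i, j] >= 0.3))
})

test_that("end-to-end prediction respects shape and range for varied configs", {
  for (cfgargs in list(list(image_size = 16, base_width = 2, n_levels = 2),
                       list(image_size = 32, base_width = 2, n_levels = 3,
                            upsample = "nearest"))) {
    cfg <- do.call(model_config, cfgargs)
    m <- init_model(cfg, seed = 3)
    ep <- generate_episode(phantom_config(image_size = cfg$image_size,
                                          seed = 4))
    out <- predict_episode(m, ep)
    expect_equal(dim(out$prob), dim(ep$query_image))
    expect_true(all(out$prob > 0 & out$prob < 1))
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$similarity >= 0 & out$similarity <= 1))
  }
})

test_that("every parameter receives gradient from the combined loss", {
  ns <- asNamespace("fsseg")
  m <- tiny_model(size = 16, base = 2, levels = 2, seed = 12)
  set.seed(13)
  # nudge away from zero-initialised ReLU kinks, and give the narrow
  # (one-unit) excitation bottlenecks a positive bias so none is dead by
  # accident of the random draw -- this checks connectivity, not the init
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
  for (nm in grep("\\.w1$", names(m$params), value = TRUE))
    m$params[[nm]] <- m$params[[nm]] * 0.2
  for (nm in grep("\\.b1$", names(m$params), value = TRUE))
    m$params[[nm]] <- abs(m$params[[nm]]) + 0.5
  nonzero <- lapply(m$params, function(p) FALSE)
  for (s in 14:15) {
    ep <- generate_episode(phantom_config(image_size = 16, seed = s))
    t <- ns$ad_tape()
    L <- ns$ad_leaves(t, m$params)
    out <- ns$forward_episode_ad(t, ns$leaf_at(L), ep, m$config, "eval")
    p2 <- ns$ad_reshape(t, out$pred, dim(out$pred$value)[1:2])
    loss <- ns$combined_ad(t, p2, ep$query_mask, loss_weights(),
                           focal_params(), tversky_params())
    ns$ad_backward(t, loss$total)
    g <- ns$ad_grads(L)
    for (nm in names(g)) nonzero[[nm]] <- nonzero[[nm]] || any(g[[nm]] != 0)
  }
  dead <- names(nonzero)[!unlist(nonzero)]
  expect_identical(dead, character(0))
})

test_that("prediction writer emits mask, probabilities, and RLE", {
  dir <- withr::local_tempdir()
  prob <- matrix(runif(64), 8)
  paths <- write_prediction(prob, file.path(dir, "pred"))
  expect_true(all(file.exists(paths)))
  rle_back <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  rec <- inverse.rle(structure(list(values = rle_back$values,
                                    lengths = rle_back$lengths),
                               class = "rle"))
  expect_equal(matrix(rec, 8), binarize(prob))
})
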