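#' Configuration for the synthetic phantom generator
#'
#' The phantom module draws CT-like 2D slice/mask pairs: one or more smooth
#' superelliptic foreground blobs (bright, mimicking soft-tissue organ
#' cross-sections) over a low-intensity textured background, with additive
#' Gaussian noise. Support and query slices of an episode come from the same
#' shape family; the query shape is perturbed by at most `shape_jitter`.
#'
#' @param image_size pixels per side (square slices), at least 16.
#' @param fg_intensity_range interval (in normalized intensity units) from
#'   which the foreground brightness offset is drawn.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param shape_jitter fractional perturbation of blob radius/ellipticity/
#'   position between the support and query slice, in `[0, 1)`.
#' @param n_blobs number of foreground components (0 gives an empty mask).
#' @param seed integer random seed; identical `(config, seed)` pairs give
#'   bit-identical output.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L,
                           fg_intensity_range = c(0.4, 0.7),
                           noise_sd = 0.03,
                           shape_jitter = 0.1,
                           n_blobs = 1L,
                           seed = 1L) {
  if (image_size < 16) stop("image_size must be >= 16")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (shape_jitter < 0 || shape_jitter >= 1)
    stop("shape_jitter must be in [0, 1)")
  if (n_blobs < 0) stop("n_blobs must be >= 0")
  if (length(fg_intensity_range) != 2 ||
      fg_intensity_range[1] > fg_intensity_range[2] ||
      fg_intensity_range[1] <= 0)
    stop("fg_intensity_range must be an increasing positive interval")
  structure(list(image_size = as.integer(image_size),
                 fg_intensity_range = fg_intensity_range,
                 noise_sd = noise_sd,
                 shape_jitter = shape_jitter,
                 n_blobs = as.integer(n_blobs),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# bilinear upscale of a coarse grid to H x W (used for background texture)
upscale_grid <- function(m, H, W) {
  src <- function(n, N) pmin(pmax((seq_len(N) - 0.5) / N * n + 0.5, 1), n)
  ys <- src(nrow(m), H); xs <- src(ncol(m), W)
  y0 <- floor(ys); y1 <- pmin(y0 + 1, nrow(m)); ay <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, ncol(m)); ax <- xs - x0
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y1, x0, drop = FALSE]
  m01 <- m[y0, x1, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(ay, H, W); wx <- matrix(ax, H, W, byrow = TRUE)
  (1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
    (1 - wy) * wx * m01 + wy * wx * m11
}

# sample one blob family: superellipse with low-order radial perturbation
sample_blob <- function(size) {
  list(cx = stats::runif(1, 0.32, 0.68) * size,
       cy = stats::runif(1, 0.32, 0.68) * size,
       a = stats::runif(1, 0.14, 0.28) * size,
       b = stats::runif(1, 0.14, 0.28) * size,
       theta = stats::runif(1, 0, pi),
       p = stats::runif(1, 1.8, 3.0),
       amp = stats::runif(3, 0, 0.06),
       phase = stats::runif(3, 0, 2 * pi))
}

# perturb a blob by a fractional jitter (query shape of an episode)
jitter_blob <- function(blob, jitter, size) {
  if (jitter <= 0) return(blob)
  r <- min(blob$a, blob$b)
  blob$a <- blob$a * (1 + stats::runif(1, -jitter, jitter))
  blob$b <- blob$b * (1 + stats::runif(1, -jitter, jitter))
  blob$cx <- blob$cx + stats::runif(1, -1, 1) * 0.25 * jitter * r
  blob$cy <- blob$cy + stats::runif(1, -1, 1) * 0.25 * jitter * r
  blob$theta <- blob$theta + stats::runif(1, -1, 1) * 0.2 * jitter
  blob
}

render_mask <- function(blobs, size) {
  mask <- matrix(0, size, size)
  if (!length(blobs)) return(mask)
  gx <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  gy <- matrix(seq_len(size) - 0.5, size, size)
  for (bl in blobs) {
    dx <- gx - bl$cx; dy <- gy - bl$cy
    u1 <- (cos(bl$theta) * dx + sin(bl$theta) * dy) / bl$a
    u2 <- (-sin(bl$theta) * dx + cos(bl$theta) * dy) / bl$b
    rho <- (abs(u1)^bl$p + abs(u2)^bl$p)^(1 / bl$p)
    phi <- atan2(u2, u1)
    bound <- 1
    for (k in seq_along(bl$amp))
      bound <- bound + bl$amp[k] * cos((k + 1) * phi + bl$phase[k])
    mask[rho <= bound] <- 1
  }
  mask
}

render_slice <- function(mask, texture, fg_offset, noise_sd) {
  img <- texture + fg_offset * mask
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(mask), 0, noise_sd),
                        nrow(mask), ncol(mask))
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, mask = mask), class = "slice_pair")
}

sample_texture <- function(size) {
  g <- max(4L, size %/% 8L)
  0.03 + upscale_grid(matrix(stats::runif(g * g, 0, 0.12), g, g), size, size)
}

#' Generate one synthetic slice/mask pair
#'
#' @param config a [phantom_config()].
#' @param seed random seed; defaults to the seed stored in `config`.
#' @return a `slice_pair`: list with `image` (H x W matrix in `[0,1]`) and
#'   `mask` (H x W binary matrix).
#' @export
generate_slice <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    size <- config$image_size
    blobs <- lapply(seq_len(config$n_blobs), function(i) sample_blob(size))
    mask <- render_mask(blobs, size)
    fg <- stats::runif(1, config$fg_intensity_range[1],
                       config$fg_intensity_range[2])
    render_slice(mask, sample_texture(size), fg, config$noise_sd)
  })
}

#' Generate a 1-shot episode (support pair plus query image and mask)
#'
#' Support and query are drawn from the same blob family; the query shapes
#' are perturbed by at most `config$shape_jitter` (radius, ellipticity,
#' position, orientation). The background texture and foreground brightness
#' are shared within the episode, so at zero jitter and zero noise the two
#' slices are identical. The query mask is retained as ground truth.
#'
#' @inheritParams generate_slice
#' @return an object of class `fss_episode`: list with `support`
#'   (a `slice_pair`), `query_image` and `query_mask`.
#' @export
generate_episode <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    size <- config$image_size
    blobs <- lapply(seq_len(config$n_blobs), function(i) sample_blob(size))
    qblobs <- lapply(blobs, jitter_blob, jitter = config$shape_jitter,
                     size = size)
    texture <- sample_texture(size)
    fg <- stats::runif(1, config$fg_intensity_range[1],
                       config$fg_intensity_range[2])
    support <- render_slice(render_mask(blobs, size), texture, fg,
                            config$noise_sd)
    query <- render_slice(render_mask(qblobs, size), texture, fg,
                          config$noise_sd)
    structure(list(support = support,
                   query_image = query$image,
                   query_mask = query$mask),
              class = "fss_episode")
  })
}

#' Deterministic stream of phantom episodes
#'
#' Returns a closure producing episode `i` as `generate_episode(config,
#' seed = config$seed + i)`, so a stream is fully reproducible from its
#' config and restarts from scratch when recreated.
#'
#' @inheritParams generate_slice
#' @return a function of no arguments returning the next `fss_episode`.
#' @export
phantom_stream <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  i <- 0L
  function() {
    i <<- i + 1L
    generate_episode(config, seed = config$seed + i)
  }
}

#' Write episodes to disk as paired PNGs with a JSON manifest
#'
#' Each episode becomes `ep<i>_support.png`, `ep<i>_support_mask.png`,
#' `ep<i>_query.png`, `ep<i>_query_mask.png` (8-bit grayscale), plus one
#' `ep<i>.rds` bundle with the numeric arrays; `manifest.json` lists files
#' and the generating seeds.
#'
#' @param config a [phantom_config()].
#' @param n_episodes number of episodes to write.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
write_episodes <- function(config, n_episodes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stream <- phantom_stream(config)
  entries <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    ep <- stream()
    base <- file.path(dir, sprintf("ep%04d", i))
    png::writePNG(ep$support$image, paste0(base, "_support.png"))
    png::writePNG(ep$support$mask, paste0(base, "_support_mask.png"))
    png::writePNG(ep$query_image, paste0(base, "_query.png"))
    png::writePNG(ep$query_mask, paste0(base, "_query_mask.png"))
    saveRDS(ep, paste0(base, ".rds"))
    entries[[i]] <- list(episode = i, seed = config$seed + i,
                         files = paste0(basename(base),
                                        c("_support.png", "_support_mask.png",
                                          "_query.png", "_query_mask.png",
                                          ".rds")))
  }
  manifest <- list(image_size = config$image_size, seed = config$seed,
                   n_episodes = n_episodes, episodes = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
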