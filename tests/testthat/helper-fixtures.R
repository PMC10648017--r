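# Shared fixtures, all built in code at test time.

# A two-class scene spec (forest vs bare land), well separated, no shadow
# or holes: the oracle scene for clustering tests.
two_class_spec <- function(size = 64, seed = 1, noise_sd = 0) {
  scene_spec(size, list(
    class_spec("forest", c(53, 87, 59, 200), diag(49, 4),
               is_forest = TRUE, proportion = 0.5),
    class_spec("bare_land", c(151, 118, 124, 45), diag(49, 4),
               proportion = 0.5)),
    forest_shadow_fraction = 0, hole_rate = 0, noise_sd = noise_sd,
    seed = seed)
}

# Brute-force Gaussian mixture log-likelihood: per-pixel weighted density
# sums via dnorm-style evaluation with explicit solve/determinant. Kept
# deliberately naive and independent of the package's Cholesky path.
brute_gmm_loglik <- function(model, pixels) {
  total <- 0
  for (i in seq_len(nrow(pixels))) {
    dens <- 0
    for (k in seq_len(model$K)) {
      sigma <- model$covariances[[k]]
      diff <- as.numeric(pixels[i, ] - model$means[k, ])
      q <- as.numeric(t(diff) %*% solve(sigma) %*% diff)
      dens <- dens + model$weights[k] *
        exp(-0.5 * q) / sqrt((2 * pi)^ncol(pixels) * det(sigma))
    }
    total <- total + log(dens)
  }
  total
}

# Brute-force per-pixel posterior argmax (0-based), independent of the
# package's log-space path.
brute_posteriors <- function(model, pixels) {
  lab <- integer(nrow(pixels))
  for (i in seq_len(nrow(pixels))) {
    post <- numeric(model$K)
    for (k in seq_len(model$K)) {
      sigma <- model$covariances[[k]]
      diff <- as.numeric(pixels[i, ] - model$means[k, ])
      q <- as.numeric(t(diff) %*% solve(sigma) %*% diff)
      post[k] <- model$weights[k] *
        exp(-0.5 * q) / sqrt((2 * pi)^ncol(pixels) * det(sigma))
    }
    lab[i] <- which.max(post) - 1L
  }
  lab
}

# A raw RGBN raster with the given constant per-band values.
constant_raster <- function(h, w, bands) {
  arr <- array(0L, c(h, w, length(bands)))
  for (b in seq_along(bands)) arr[, , b] <- bands[b]
  arr
}

# 200 ground-truth-labeled 64x64 tiles from seeded default scenes.
training_tiles <- function(n = 200, tile = 64, scene = 128,
                           seed_base = 300) {
  samples <- list()
  i <- 0
  while (length(samples) < n) {
    i <- i + 1
    sc <- generate_scene(default_scene_spec(scene, seed = seed_base + i))
    samples <- c(samples,
                 tile_image(sc$image, sc$truth$mask, tile = tile,
                            image_id = sprintf("scene%03d", i)))
  }
  samples[seq_len(n)]
}
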