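test_that("built models allocate exactly the ledger's parameter count", {
  for (b in c(1L, 2L, 3L, 5L, 8L)) {
    spec <- unet_spec(base_width = b)
    model <- build_model(spec, seed = b)
    expect_equal(model_parameter_count(model), total_parameters(spec))
  }
  # plain upsampling mode stays consistent with its own ledger
  spec_pl <- unet_spec(base_width = 4, upsample_mode = "plain_upsample")
  expect_equal(model_parameter_count(build_model(spec_pl)),
               total_parameters(spec_pl))
})

test_that("forward pass has the right shape, range, and determinism", {
  model <- build_model(unet_spec(scenario = 6), seed = 2)
  x <- array(0, c(32, 32, 1, 4))
  p1 <- forestseg:::unet_forward(model, x)$p
  expect_equal(dim(p1), c(32, 32, 1))
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- forestseg:::unet_forward(model, x)$p
  expect_identical(p1, p2)   # inference has no stochastic layers
})

test_that("weight initialization is reproducible under the seed", {
  m1 <- build_model(unet_spec(scenario = 6), seed = 7)
  m2 <- build_model(unet_spec(scenario = 6), seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(unet_spec(scenario = 6), seed = 8)
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  spec <- unet_spec(base_width = 2, depth = 2, in_channels = 4,
                    dropout_rate = 0)
  model <- build_model(spec, seed = 5)
  # move biases off zero: ReLU pre-activations at exactly 0 are kinks
  # where one-sided numerical differences are meaningless
  for (nm in grep("_b$", names(model$params), value = TRUE)) {
    model$params[[nm]] <- model$params[[nm]] +
      stats::rnorm(length(model$params[[nm]]), sd = 0.05)
  }
  x <- array(runif(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  y <- array(rbinom(8 * 8 * 2, 1, 0.5), c(8, 8, 2))
  fw <- forestseg:::unet_forward(model, x, train = TRUE)
  grads <- forestseg:::unet_backward(model, fw$cache,
                                     (fw$p - y) / length(y))
  eps <- 1e-6
  for (nm in names(model$params)) {
    p0 <- model$params[[nm]]
    for (j in seq_len(min(3L, length(p0)))) {
      m2 <- model
      m2$params[[nm]][j] <- p0[j] + eps
      lp <- bce_loss(y, forestseg:::unet_forward(m2, x)$p)
      m2$params[[nm]][j] <- p0[j] - eps
      lm <- bce_loss(y, forestseg:::unet_forward(m2, x)$p)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-3,
                   info = nm)
    }
  }
})

test_that("binary cross-entropy matches closed forms and an oracle", {
  expect_equal(bce_loss(1, 1 - 1e-12), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), -log(0.9))
  set.seed(31)
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  manual <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 64
  expect_equal(bce_loss(y, p), manual, tolerance = 1e-10)
  expect_error(bce_loss(c(1, 0), 0.5), class = "forestseg_input_error")
})

test_that("the Adam reference step follows the standard recurrence", {
  cfg <- list(alpha = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-12)
  # first step with constant gradient: theta moves by ~ -alpha * sign(g)
  s1 <- adam_reference_step(1, 4, config = cfg)
  expect_equal(s1$theta, 1 - 0.1, tolerance = 1e-9)
  s1n <- adam_reference_step(1, -0.25, config = cfg)
  expect_equal(s1n$theta, 1 + 0.1, tolerance = 1e-9)
  # zero gradient with zero state leaves theta unchanged
  s0 <- adam_reference_step(2, 0, config = cfg)
  expect_equal(s0$theta, 2)
  # two steps with g = 1 against a hand-rolled scalar recurrence
  cfg2 <- list(alpha = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  m <- 0; v <- 0; th <- 0.5
  for (t in 1:2) {
    m <- 0.9 * m + 0.1 * 1
    v <- 0.999 * v + 0.001 * 1
    th <- th - 0.1 * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
  }
  s <- adam_reference_step(0.5, 1, config = cfg2)
  s <- adam_reference_step(s$theta, 1, s$state, config = cfg2)
  expect_equal(s$theta, th, tolerance = 1e-12)
})

test_that("the training-loop optimizer reproduces the reference on a quadratic", {
  # loss 0.5 * theta^2, gradient theta, 10 steps
  cfg <- train_config(alpha = 0.05, epochs = 1)
  params <- list(theta = 2)
  state <- forestseg:::adam_state_init(params)
  ref_theta <- 2; ref_state <- NULL
  ref_cfg <- list(alpha = 0.05, beta1 = cfg$beta1, beta2 = cfg$beta2,
                  eps = cfg$eps)
  for (i in 1:10) {
    upd <- forestseg:::adam_update(params, list(theta = params$theta),
                                   state, cfg)
    params <- upd$params; state <- upd$state
    r <- adam_reference_step(ref_theta, ref_theta, ref_state, ref_cfg)
    ref_theta <- r$theta; ref_state <- r$state
  }
  expect_equal(params$theta, ref_theta, tolerance = 1e-6)
})

test_that("segmentation metrics match confusion-matrix arithmetic", {
  perfect <- segmentation_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  expect_equal(perfect$pixel_accuracy, 1)
  expect_equal(perfect$f1_score, 1)
  allneg <- segmentation_metrics(c(1, 0, 0), c(0.1, 0.1, 0.1))
  expect_equal(allneg$f1_score, 0)
  # worked case: TP=2, FP=1, FN=1, TN=0
  m <- segmentation_metrics(c(1, 1, 1, 0), c(0.9, 0.8, 0.1, 0.9))
  expect_equal(m$confusion, c(tp = 2, fp = 1, fn = 1, tn = 0))
  expect_equal(m$f1_score, 2 / 3)
  expect_equal(m$pixel_accuracy, 1 / 2)
})

test_that("training is seeded, recorded, and improves on separable tiles", {
  tiles <- training_tiles(24, tile = 32, scene = 64, seed_base = 700)
  model <- build_model(unet_spec(scenario = 6), seed = 1)
  cfg <- train_config(alpha = 1e-2, epochs = 2, batch_size = 8, seed = 4)
  r1 <- train_model(model, tiles, cfg)
  expect_equal(nrow(r1$history), 2L)
  expect_true(all(is.finite(r1$history$train_loss)))
  expect_lt(r1$history$train_loss[2], r1$history$train_loss[1])
  # same seed, same data -> identical history
  r2 <- train_model(model, tiles, cfg)
  expect_identical(r1$history, r2$history)
  # zero epochs: empty history, untouched weights
  r0 <- train_model(model, tiles, train_config(epochs = 0))
  expect_equal(nrow(r0$history), 0L)
  expect_identical(r0$model$params, model$params)
})

test_that("evaluation aggregates over batches consistently", {
  tiles <- training_tiles(6, tile = 32, scene = 64, seed_base = 800)
  model <- build_model(unet_spec(scenario = 6), seed = 3)
  ev1 <- evaluate_model(model, tiles, batch_size = 2)
  ev2 <- evaluate_model(model, tiles, batch_size = 6)
  expect_equal(ev1$pixel_accuracy, ev2$pixel_accuracy)
  expect_equal(ev1$mean_bce_loss, ev2$mean_bce_loss, tolerance = 1e-12)
  expect_true(ev1$pixel_accuracy >= 0 && ev1$pixel_accuracy <= 1)
  expect_error(evaluate_model(model, list()),
               class = "forestseg_input_error")
})

test_that("model weights round trip through a checkpoint directory", {
  model <- build_model(unet_spec(scenario = 6), seed = 6)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_equal(back$params, model$params)
  expect_equal(back$spec$base_width, 2L)
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  expect_identical(forestseg:::unet_forward(model, x)$p,
                   forestseg:::unet_forward(back, x)$p)
})
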