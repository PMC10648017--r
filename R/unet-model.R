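# Building, training, and evaluating the segmentation network.

param_names <- function(spec) {
  nm <- character(0)
  for (i in seq_along(spec$enc_widths)) {
    nm <- c(nm, sprintf("enc%d_conv%d_%s", i, rep(1:2, each = 2),
                        c("W", "b")))
  }
  nm <- c(nm, sprintf("bridge_conv%d_%s", rep(1:2, each = 2), c("W", "b")))
  for (i in seq_along(spec$dec_widths)) {
    if (spec$upsample_mode == "transposed_halving") {
      nm <- c(nm, sprintf("dec%d_upconv_%s", i, c("W", "b")))
    }
    nm <- c(nm, sprintf("dec%d_conv%d_%s", i, rep(1:2, each = 2),
                        c("W", "b")))
  }
  c(nm, "out_W", "out_b")
}

#' Build a trainable segmentation model from a spec
#'
#' Instantiates every weight tensor of the architecture (He-normal
#' initialization for the ReLU convolutions, scaled-normal for the output
#' layer, zero biases) and asserts that the framework-level parameter
#' count — the summed length of every tensor actually allocated — equals
#' the analytic [count_parameters()] ledger total. A mismatch is an
#' internal consistency error and fails loudly.
#'
#' @param spec A [unet_spec()].
#' @param seed Seed for the weight initialization.
#' @return A `unet_model`: list with `spec`, `params` (named list of
#'   matrices/vectors), and `seed`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    he <- function(nrow_, ncol_, fan_in) {
      matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)),
             nrow_, ncol_)
    }
    c_in <- spec$in_channels
    for (i in seq_along(spec$enc_widths)) {
      w <- spec$enc_widths[i]
      p[[sprintf("enc%d_conv1_W", i)]] <- he(9L * c_in, w, 9 * c_in)
      p[[sprintf("enc%d_conv1_b", i)]] <- numeric(w)
      p[[sprintf("enc%d_conv2_W", i)]] <- he(9L * w, w, 9 * w)
      p[[sprintf("enc%d_conv2_b", i)]] <- numeric(w)
      c_in <- w
    }
    bw <- spec$bridge_width
    p[["bridge_conv1_W"]] <- he(9L * c_in, bw, 9 * c_in)
    p[["bridge_conv1_b"]] <- numeric(bw)
    p[["bridge_conv2_W"]] <- he(9L * bw, bw, 9 * bw)
    p[["bridge_conv2_b"]] <- numeric(bw)
    c_cur <- bw
    for (i in seq_along(spec$dec_widths)) {
      w <- spec$dec_widths[i]
      if (spec$upsample_mode == "transposed_halving") {
        p[[sprintf("dec%d_upconv_W", i)]] <- he(c_cur, 4L * w, 4 * c_cur)
        p[[sprintf("dec%d_upconv_b", i)]] <- numeric(w)
        conv1_in <- 2L * w
      } else {
        conv1_in <- c_cur + w
      }
      p[[sprintf("dec%d_conv1_W", i)]] <- he(9L * conv1_in, w, 9 * conv1_in)
      p[[sprintf("dec%d_conv1_b", i)]] <- numeric(w)
      p[[sprintf("dec%d_conv2_W", i)]] <- he(9L * w, w, 9 * w)
      p[[sprintf("dec%d_conv2_b", i)]] <- numeric(w)
      c_cur <- w
    }
    p[["out_W"]] <- matrix(stats::rnorm(c_cur, sd = sqrt(1 / c_cur)),
                           c_cur, 1L)
    p[["out_b"]] <- 0
    p
  })
  built <- model_parameter_count(params)
  ledger_total <- attr(count_parameters(spec), "total_parameters")
  if (built != ledger_total) {
    fs_abort(sprintf(
      "built model has %.0f parameters but the ledger says %.0f",
      built, ledger_total), "forestseg_internal_consistency_error")
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' Framework-reported trainable-parameter count
#'
#' Sums the length of every allocated weight and bias tensor of a built
#' model — the count an ML framework would report — independent of the
#' analytic ledger.
#'
#' @param x A `unet_model` or its `params` list.
#' @return Total number of trainable scalars.
#' @export
model_parameter_count <- function(x) {
  if (inherits(x, "unet_model")) x <- x$params
  sum(vapply(x, length, numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> base %d (%s), %s trainable parameters\n",
              x$spec$base_width, x$spec$upsample_mode,
              format(model_parameter_count(x), big.mark = ",")))
  invisible(x)
}

# Full forward pass. x: (H, W, N, C) double in [0, 1]. Returns predicted
# probabilities (H, W, N) and, when `train = TRUE`, the caches needed by
# the backward pass. Dropout is applied after the encoding path; callers
# own the RNG state.
unet_forward <- function(model, x, train = FALSE) {
  spec <- model$spec
  p <- model$params
  depth <- spec$depth
  cache <- list(blocks = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    d_in1 <- dim(h)
    cv1 <- conv3_forward(h, p[[sprintf("enc%d_conv1_W", i)]],
                         p[[sprintf("enc%d_conv1_b", i)]])
    r1 <- relu_forward(cv1$out)
    d_in2 <- dim(r1$out)
    cv2 <- conv3_forward(r1$out, p[[sprintf("enc%d_conv2_W", i)]],
                         p[[sprintf("enc%d_conv2_b", i)]])
    r2 <- relu_forward(cv2$out)
    skips[[i]] <- r2$out
    pool <- maxpool2_forward(r2$out)
    h <- pool$out
    cache$blocks[[i]] <- list(cols1 = cv1$cols, d1 = d_in1, mask1 = r1$mask,
                              cols2 = cv2$cols, d2 = d_in2, mask2 = r2$mask,
                              pool = pool)
  }
  if (train && spec$dropout_rate > 0) {
    keep <- 1 - spec$dropout_rate
    dmask <- array((stats::runif(length(h)) < keep) / keep, dim(h))
    h <- h * dmask
    cache$dropout <- dmask
  }
  d_inb1 <- dim(h)
  cvb1 <- conv3_forward(h, p[["bridge_conv1_W"]], p[["bridge_conv1_b"]])
  rb1 <- relu_forward(cvb1$out)
  d_inb2 <- dim(rb1$out)
  cvb2 <- conv3_forward(rb1$out, p[["bridge_conv2_W"]], p[["bridge_conv2_b"]])
  rb2 <- relu_forward(cvb2$out)
  h <- rb2$out
  cache$bridge <- list(cols1 = cvb1$cols, d1 = d_inb1, mask1 = rb1$mask,
                       cols2 = cvb2$cols, d2 = d_inb2, mask2 = rb2$mask)
  for (i in seq_len(depth)) {
    s <- skips[[depth + 1L - i]]
    if (spec$upsample_mode == "transposed_halving") {
      up <- upconv2_forward(h, p[[sprintf("dec%d_upconv_W", i)]],
                            p[[sprintf("dec%d_upconv_b", i)]])
      ru <- relu_forward(up$out)
      u <- ru$out
      upcache <- list(up = up, mask_u = ru$mask)
    } else {
      up <- upsample2_forward(h)
      u <- up$out
      upcache <- list(up = up)
    }
    cat_in <- concat_channels(u, s)
    d_in1 <- dim(cat_in)
    cv1 <- conv3_forward(cat_in, p[[sprintf("dec%d_conv1_W", i)]],
                         p[[sprintf("dec%d_conv1_b", i)]])
    r1 <- relu_forward(cv1$out)
    d_in2 <- dim(r1$out)
    cv2 <- conv3_forward(r1$out, p[[sprintf("dec%d_conv2_W", i)]],
                         p[[sprintf("dec%d_conv2_b", i)]])
    r2 <- relu_forward(cv2$out)
    h <- r2$out
    cache$dec[[i]] <- c(upcache, list(
      c_up = dim(u)[4], cols1 = cv1$cols, d1 = d_in1, mask1 = r1$mask,
      cols2 = cv2$cols, d2 = d_in2, mask2 = r2$mask))
  }
  d <- dim(h)
  hm <- matrix(h, d[1] * d[2] * d[3], d[4])
  logits <- array(hm %*% p[["out_W"]] + p[["out_b"]], d[1:3])
  cache$out <- list(hm = hm, d_last = d)
  list(p = sigmoid(logits), cache = if (train) cache else NULL)
}

# Backward pass from dlogits (gradient of the loss w.r.t. the logits,
# shape (H, W, N)). Returns the named gradient list.
unet_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  p <- model$params
  depth <- spec$depth
  g <- list()

  d_last <- cache$out$d_last
  dY <- matrix(dlogits, prod(d_last[1:3]), 1L)
  g[["out_W"]] <- crossprod(cache$out$hm, dY)
  g[["out_b"]] <- sum(dY)
  dh <- array(dY %*% t(p[["out_W"]]), d_last)

  dskips <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    bc <- cache$dec[[i]]
    dh <- relu_backward(dh, bc$mask2)
    bk <- conv3_backward(dh, bc$cols2, p[[sprintf("dec%d_conv2_W", i)]],
                         bc$d2)
    g[[sprintf("dec%d_conv2_W", i)]] <- bk$dW
    g[[sprintf("dec%d_conv2_b", i)]] <- bk$db
    dh <- relu_backward(bk$dx, bc$mask1)
    bk <- conv3_backward(dh, bc$cols1, p[[sprintf("dec%d_conv1_W", i)]],
                         bc$d1)
    g[[sprintf("dec%d_conv1_W", i)]] <- bk$dW
    g[[sprintf("dec%d_conv1_b", i)]] <- bk$db
    dcat <- bk$dx
    c_up <- bc$c_up
    du <- dcat[, , , seq_len(c_up), drop = FALSE]
    dskips[[depth + 1L - i]] <-
      dcat[, , , c_up + seq_len(dim(dcat)[4] - c_up), drop = FALSE]
    if (spec$upsample_mode == "transposed_halving") {
      du <- relu_backward(du, bc$mask_u)
      bk <- upconv2_backward(du, bc$up, p[[sprintf("dec%d_upconv_W", i)]])
      g[[sprintf("dec%d_upconv_W", i)]] <- bk$dW
      g[[sprintf("dec%d_upconv_b", i)]] <- bk$db
      dh <- bk$dx
    } else {
      dh <- upsample2_backward(du, bc$up)
    }
  }

  bc <- cache$bridge
  dh <- relu_backward(dh, bc$mask2)
  bk <- conv3_backward(dh, bc$cols2, p[["bridge_conv2_W"]], bc$d2)
  g[["bridge_conv2_W"]] <- bk$dW
  g[["bridge_conv2_b"]] <- bk$db
  dh <- relu_backward(bk$dx, bc$mask1)
  bk <- conv3_backward(dh, bc$cols1, p[["bridge_conv1_W"]], bc$d1)
  g[["bridge_conv1_W"]] <- bk$dW
  g[["bridge_conv1_b"]] <- bk$db
  dh <- bk$dx
  if (!is.null(cache$dropout)) dh <- dh * cache$dropout

  for (i in rev(seq_len(depth))) {
    bc <- cache$blocks[[i]]
    dh <- maxpool2_backward(dh, bc$pool) + dskips[[i]]
    dh <- relu_backward(dh, bc$mask2)
    bk <- conv3_backward(dh, bc$cols2, p[[sprintf("enc%d_conv2_W", i)]],
                         bc$d2)
    g[[sprintf("enc%d_conv2_W", i)]] <- bk$dW
    g[[sprintf("enc%d_conv2_b", i)]] <- bk$db
    dh <- relu_backward(bk$dx, bc$mask1)
    bk <- conv3_backward(dh, bc$cols1, p[[sprintf("enc%d_conv1_W", i)]],
                         bc$d1)
    g[[sprintf("enc%d_conv1_W", i)]] <- bk$dW
    g[[sprintf("enc%d_conv1_b", i)]] <- bk$db
    dh <- bk$dx
  }
  g
}

#' Training configuration
#'
#' @param alpha Learning rate. The default `1e-4` suits long training
#'   schedules (thousands of optimizer steps); short desk-scale runs
#'   typically need a larger rate, since Adam's per-parameter step is
#'   bounded by `alpha` (see the methods vignette).
#' @param batch_size Samples per optimizer step (default 16).
#' @param epochs Training epochs.
#' @param beta1,beta2 Adam moment decay rates (0.9, 0.999).
#' @param eps Adam division guard.
#' @param seed Seed for weight initialization order, shuffling, dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(alpha = 1e-4, batch_size = 16L, epochs = 10L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  stopifnot(alpha > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            eps > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(alpha = alpha, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), loss = "bce"),
            class = "train_config")
}

# One Adam update over a named list of parameter tensors; the same
# recurrence as adam_reference_step, vectorized per tensor. Used by the
# training loop and verifiable against the reference on scalar problems.
adam_update <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  bc1 <- 1 - config$beta1^state$t
  bc2 <- 1 - config$beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * gnm
    state$v[[nm]] <- config$beta2 * state$v[[nm]] +
      (1 - config$beta2) * gnm^2
    params[[nm]] <- params[[nm]] - config$alpha * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + config$eps)
  }
  list(params = params, state = state)
}

adam_state_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

#' Pixel-wise segmentation metrics
#'
#' Thresholds predicted probabilities and scores them against binary
#' labels: pixel accuracy, F1 with forest (1) as the positive class
#' (`2 TP / (2 TP + FP + FN)`), and mean binary cross-entropy.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return List `pixel_accuracy`, `f1_score`, `mean_bce_loss`,
#'   `confusion` (tp, fp, fn, tn).
#' @export
segmentation_metrics <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) {
    fs_abort("labels and predictions have different lengths",
             "forestseg_input_error")
  }
  pred <- p >= threshold
  truth <- y == 1
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  list(pixel_accuracy = (tp + tn) / length(y),
       f1_score = if (2 * tp + fp + fn == 0) 1
                  else 2 * tp / (2 * tp + fp + fn),
       mean_bce_loss = bce_loss(y, p),
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

# Stack tile samples into network tensors: x (H, W, N, C) scaled to
# [0, 1], y (H, W, N) binary.
batch_tensor <- function(samples) {
  n <- length(samples)
  dp <- dim(samples[[1]]$patch)
  x <- array(0, c(dp[1], dp[2], n, dp[3]))
  y <- array(0, c(dp[1], dp[2], n))
  for (i in seq_len(n)) {
    x[, , i, ] <- raw_to_double(samples[[i]]$patch) / 255
    y[, , i] <- raw_to_double(samples[[i]]$label)
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Minibatch Adam on binary cross-entropy with seeded shuffling and
#' dropout; per-epoch training and validation loss/accuracy are recorded.
#' A non-finite loss aborts with a divergence diagnostic.
#'
#' @param model A `unet_model` from [build_model()].
#' @param data A `dataset_split` (train/validation used) or a plain list
#'   of `tile_sample`s (no validation column).
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history` (data frame `epoch`,
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_model <- function(model, data, config = train_config()) {
  train_samples <- if (inherits(data, "dataset_split")) data$train else data
  val_samples <- if (inherits(data, "dataset_split")) data$validation
                 else list()
  if (!length(train_samples)) {
    fs_abort("training set is empty", "forestseg_input_error")
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (config$epochs == 0L) {
    return(list(model = model, history = history))
  }
  params <- model$params
  state <- adam_state_init(params)
  n <- length(train_samples)
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0; ep_pix <- 0
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + config$batch_size - 1L, n)]
        bt <- batch_tensor(train_samples[idx])
        fw <- unet_forward(model, bt$x, train = TRUE)
        loss <- bce_loss(bt$y, fw$p)
        if (!is.finite(loss)) {
          fs_abort(sprintf(
            "training diverged (non-finite loss) at epoch %d", epoch),
            "forestseg_divergence_error")
        }
        npix <- length(bt$y)
        ep_loss <- ep_loss + loss * npix
        ep_correct <- ep_correct + sum((fw$p >= 0.5) == (bt$y == 1))
        ep_pix <- ep_pix + npix
        dlogits <- (fw$p - bt$y) / npix
        grads <- unet_backward(model, fw$cache, dlogits)
        upd <- adam_update(params, grads, state, config)
        params <- upd$params
        state <- upd$state
        model$params <- params
      }
      val <- if (length(val_samples)) {
        ev <- evaluate_model(model, val_samples)
        c(ev$mean_bce_loss, ev$pixel_accuracy)
      } else {
        c(NA_real_, NA_real_)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / ep_pix,
        train_acc = ep_correct / ep_pix,
        val_loss = val[1], val_acc = val[2]))
    }
  })
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model on tile samples
#'
#' @param model A `unet_model`.
#' @param samples Non-empty list of `tile_sample`s.
#' @param threshold Probability threshold for the binary mask (0.5).
#' @param batch_size Forward-pass batch size.
#' @return An `eval_result`: `pixel_accuracy`, `f1_score` (forest as the
#'   positive class), `mean_bce_loss`, `threshold`.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           batch_size = 16L) {
  if (!length(samples)) {
    fs_abort("evaluate needs at least one sample", "forestseg_input_error")
  }
  ys <- ps <- vector("list", 0L)
  starts <- seq(1L, length(samples), by = batch_size)
  for (s0 in starts) {
    idx <- s0:min(s0 + batch_size - 1L, length(samples))
    bt <- batch_tensor(samples[idx])
    fw <- unet_forward(model, bt$x, train = FALSE)
    ys[[length(ys) + 1L]] <- as.vector(bt$y)
    ps[[length(ps) + 1L]] <- as.vector(fw$p)
  }
  m <- segmentation_metrics(unlist(ys), unlist(ps), threshold = threshold)
  structure(c(m, list(threshold = threshold)), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> accuracy %.5f, F1 %.5f, BCE %.5f (threshold %.2f)\n",
    x$pixel_accuracy, x$f1_score, x$mean_bce_loss, x$threshold))
  invisible(x)
}

#' Predict a forest-probability map for one image or patch
#'
#' @param model A `unet_model`.
#' @param image A [multiband_image()] whose extent is divisible by
#'   `2^depth`.
#' @return `H x W` matrix of forest probabilities.
#' @export
predict_probability <- function(model, image) {
  stopifnot(inherits(image, "multiband_image"))
  d <- dim(image$pixels)
  x <- array(pixel_array(image) / 255, c(d[1], d[2], 1L, d[3]))
  unet_forward(model, x, train = FALSE)$p[, , 1]
}

#' Save / load model weights
#'
#' Weights are stored as one NPY array per tensor plus a YAML file holding
#' the architecture spec, under a directory.
#'
#' @param model A `unet_model`.
#' @param dir Checkpoint directory.
#' @return `save_model()` returns `dir` invisibly; `load_model()` the
#'   restored `unet_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- model$spec
  yaml::write_yaml(list(base_width = sp$base_width, depth = sp$depth,
                        in_channels = sp$in_channels,
                        upsample_mode = sp$upsample_mode,
                        dropout_rate = sp$dropout_rate,
                        seed = model$seed),
                   file.path(dir, "spec.yaml"))
  for (nm in names(model$params)) {
    x <- model$params[[nm]]
    write_npy(if (is.matrix(x)) x else as.double(x),
              file.path(dir, paste0(nm, ".npy")))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  spec <- unet_spec(base_width = meta$base_width, depth = meta$depth,
                    in_channels = meta$in_channels,
                    upsample_mode = meta$upsample_mode,
                    dropout_rate = meta$dropout_rate)
  model <- build_model(spec, seed = meta$seed %||% 1L)
  for (nm in names(model$params)) {
    x <- read_npy(file.path(dir, paste0(nm, ".npy")))
    if (is.matrix(model$params[[nm]])) {
      model$params[[nm]] <- matrix(x, nrow(model$params[[nm]]),
                                   ncol(model$params[[nm]]))
    } else {
      model$params[[nm]] <- as.double(x)
    }
  }
  model
}
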