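# Dense-linear-algebra building blocks for the segmentation network.
#
# Batches are held as 4-d arrays in (H, W, N, C) layout: slicing a spatial
# window then flattening gives an (H*W*N) x C matrix whose rows are
# consistent across window offsets, which turns every convolution into one
# BLAS matrix product (the im2col trick). All convolutions use zero
# padding ("same" output size).

# im2col for a 3x3 window: (H*W*N) x (9*C) matrix; column block o holds
# channel columns for window offset o (row-major offsets).
im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  padded <- array(0, c(H + 2L, W + 2L, N, C))
  padded[2:(H + 1L), 2:(W + 1L), , ] <- x
  out <- matrix(0, H * W * N, 9L * C)
  o <- 0L
  for (di in 0:2) {
    for (dj in 0:2) {
      o <- o + 1L
      block <- padded[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
      out[, (o - 1L) * C + seq_len(C)] <- matrix(block, H * W * N, C)
    }
  }
  out
}

# Adjoint of im2col3: scatter-add column blocks back to (H, W, N, C).
col2im3 <- function(cols, H, W, N, C) {
  padded <- array(0, c(H + 2L, W + 2L, N, C))
  o <- 0L
  for (di in 0:2) {
    for (dj in 0:2) {
      o <- o + 1L
      block <- array(cols[, (o - 1L) * C + seq_len(C)], c(H, W, N, C))
      padded[di + seq_len(H), dj + seq_len(W), , ] <-
        padded[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] + block
    }
  }
  padded[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

# 3x3 same-padded convolution. W: (9*C_in) x C_out, b: length C_out.
conv3_forward <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2L, b, "+")
  list(out = array(y, c(d[1], d[2], d[3], ncol(W))), cols = cols)
}

conv3_backward <- function(dout, cols, W, d_in) {
  H <- d_in[1]; W_ <- d_in[2]; N <- d_in[3]; C <- d_in[4]
  dY <- matrix(dout, H * W_ * N, ncol(W))
  list(dW = crossprod(cols, dY),
       db = colSums(dY),
       dx = col2im3(dY %*% t(W), H, W_, N, C))
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# 2x2 max pooling with stride 2. Ties route to the first window position.
maxpool2_forward <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1], by = 2L); rj <- seq(1L, d[2], by = 2L)
  s <- list(x[ri, rj, , , drop = FALSE],
            x[ri + 1L, rj, , , drop = FALSE],
            x[ri, rj + 1L, , , drop = FALSE],
            x[ri + 1L, rj + 1L, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  a1 <- s[[1]] == out
  a2 <- (s[[2]] == out) & !a1
  a3 <- (s[[3]] == out) & !a1 & !a2
  a4 <- !(a1 | a2 | a3)
  list(out = out, routes = list(a1, a2, a3, a4), d_in = d)
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$d_in
  dx <- array(0, d)
  ri <- seq(1L, d[1], by = 2L); rj <- seq(1L, d[2], by = 2L)
  dx[ri, rj, , ] <- dout * cache$routes[[1]]
  dx[ri + 1L, rj, , ] <- dout * cache$routes[[2]]
  dx[ri, rj + 1L, , ] <- dout * cache$routes[[3]]
  dx[ri + 1L, rj + 1L, , ] <- dout * cache$routes[[4]]
  dx
}

# 2x2 stride-2 transposed convolution. W: C_in x (4*C_out), b: C_out.
# Output offset blocks: 1 = (0,0), 2 = (1,0), 3 = (0,1), 4 = (1,1).
upconv2_forward <- function(x, W, b) {
  d <- dim(x)
  H <- d[1]; W_ <- d[2]; N <- d[3]; C_in <- d[4]
  C_out <- ncol(W) %/% 4L
  xm <- matrix(x, H * W_ * N, C_in)
  y <- xm %*% W
  out <- array(0, c(2L * H, 2L * W_, N, C_out))
  ri <- seq(1L, 2L * H, by = 2L); rj <- seq(1L, 2L * W_, by = 2L)
  idx <- list(list(ri, rj), list(ri + 1L, rj),
              list(ri, rj + 1L), list(ri + 1L, rj + 1L))
  for (o in 1:4) {
    block <- sweep(y[, (o - 1L) * C_out + seq_len(C_out), drop = FALSE],
                   2L, b, "+")
    out[idx[[o]][[1]], idx[[o]][[2]], , ] <-
      array(block, c(H, W_, N, C_out))
  }
  list(out = out, xm = xm, d_in = d)
}

upconv2_backward <- function(dout, cache, W) {
  d <- cache$d_in
  H <- d[1]; W_ <- d[2]; N <- d[3]; C_in <- d[4]
  C_out <- ncol(W) %/% 4L
  ri <- seq(1L, 2L * H, by = 2L); rj <- seq(1L, 2L * W_, by = 2L)
  idx <- list(list(ri, rj), list(ri + 1L, rj),
              list(ri, rj + 1L), list(ri + 1L, rj + 1L))
  dW <- matrix(0, C_in, 4L * C_out)
  db <- numeric(C_out)
  dxm <- matrix(0, H * W_ * N, C_in)
  for (o in 1:4) {
    dblock <- matrix(dout[idx[[o]][[1]], idx[[o]][[2]], , , drop = FALSE],
                     H * W_ * N, C_out)
    cols <- (o - 1L) * C_out + seq_len(C_out)
    dW[, cols] <- crossprod(cache$xm, dblock)
    db <- db + colSums(dblock)
    dxm <- dxm + dblock %*% t(W[, cols, drop = FALSE])
  }
  list(dW = dW, db = db, dx = array(dxm, d))
}

# Parameter-free nearest-neighbor 2x upsampling.
upsample2_forward <- function(x) {
  d <- dim(x)
  out <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  ri <- seq(1L, 2L * d[1], by = 2L); rj <- seq(1L, 2L * d[2], by = 2L)
  out[ri, rj, , ] <- x; out[ri + 1L, rj, , ] <- x
  out[ri, rj + 1L, , ] <- x; out[ri + 1L, rj + 1L, , ] <- x
  list(out = out, d_in = d)
}

upsample2_backward <- function(dout, cache) {
  d <- cache$d_in
  ri <- seq(1L, 2L * d[1], by = 2L); rj <- seq(1L, 2L * d[2], by = 2L)
  dout[ri, rj, , , drop = FALSE] + dout[ri + 1L, rj, , , drop = FALSE] +
    dout[ri, rj + 1L, , , drop = FALSE] +
    dout[ri + 1L, rj + 1L, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]`, with predicted
#' probabilities clamped to `[eps, 1 - eps]` to avoid `log(0)`.
#'
#' @param y Binary labels (0/1), any shape.
#' @param p Predicted probabilities, same shape as `y`.
#' @param eps Probability clamp (default `1e-7`).
#' @return Non-negative mean loss.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) {
    fs_abort("labels and predictions have different lengths",
             "forestseg_input_error")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' One reference Adam update
#'
#' The scalar/vector recurrence of adaptive moment estimation: biased
#' first and second moment updates
#' `m' = beta1 m + (1 - beta1) g`, `v' = beta2 v + (1 - beta2) g^2`,
#' bias corrections `m'/(1 - beta1^t)`, `v'/(1 - beta2^t)`, and the step
#' `theta - alpha mhat / (sqrt(vhat) + eps)`. This standalone recurrence
#' is the oracle against which the training loop's vectorized optimizer is
#' verified.
#'
#' @param theta Current parameter value(s).
#' @param g Gradient of the loss at `theta`.
#' @param state List `m`, `v`, `t` (zeros and 0 before the first step).
#' @param config List with `alpha`, `beta1` (0.9), `beta2` (0.999), `eps`.
#' @return List `theta` (updated) and `state` (updated, `t` incremented).
#' @export
adam_reference_step <- function(theta, g, state = NULL,
                                config = list(alpha = 1e-3, beta1 = 0.9,
                                              beta2 = 0.999, eps = 1e-8)) {
  if (is.null(state)) {
    state <- list(m = numeric(length(theta)), v = numeric(length(theta)),
                  t = 0L)
  }
  t1 <- state$t + 1L
  m <- config$beta1 * state$m + (1 - config$beta1) * g
  v <- config$beta2 * state$v + (1 - config$beta2) * g^2
  mhat <- m / (1 - config$beta1^t1)
  vhat <- v / (1 - config$beta2^t1)
  list(theta = theta - config$alpha * mhat / (sqrt(vhat) + config$eps),
       state = list(m = m, v = v, t = t1))
}
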