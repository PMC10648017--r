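# The downscaled U-Net family: architecture descriptors and the analytic
# kernel / trainable-parameter ledger.

#' Describe a member of the downscaled U-Net family
#'
#' The family keeps the classic symmetric shape — four encoder blocks of
#' two 3x3 same-padded convolutions each, a two-convolution bridge, four
#' decoder blocks fed by 2x2 upsampling and concatenation skip
#' connections, and a 1x1 sigmoid output — while scaling every width from
#' a single `base_width` `b`: encoders `(b, 2b, 4b, 8b)`, bridge `16b`,
#' decoders `(8b, 4b, 2b, b)`. The six downscaling scenarios use base
#' widths 64, 32, 16, 8, 4, 2.
#'
#' @param base_width First-encoder kernel count (`b >= 1`). Ignored when
#'   `scenario` is given.
#' @param scenario Scenario number 1-6, mapping to `base_width`
#'   `64 / 2^(s-1)`.
#' @param depth Number of encoder blocks (default 4).
#' @param in_channels Input bands (default 4, RGBN).
#' @param upsample_mode `"transposed_halving"` (default): learnable 2x2
#'   transposed convolution that halves the channel count before
#'   concatenation. `"plain_upsample"`: parameter-free nearest-neighbor
#'   upsampling, so the first decoder convolution sees the full incoming
#'   channels plus the skip; its ledger carries zero-parameter upsampling
#'   rows.
#' @param dropout_rate Dropout after the encoding path (default 0.5).
#' @return A `unet_spec` with derived `enc_widths`, `bridge_width`,
#'   `dec_widths`.
#' @export
unet_spec <- function(base_width = NULL, scenario = NULL, depth = 4L,
                      in_channels = 4L,
                      upsample_mode = c("transposed_halving",
                                        "plain_upsample"),
                      dropout_rate = 0.5) {
  upsample_mode <- match.arg(upsample_mode)
  if (!is.null(scenario)) {
    if (!scenario %in% 1:6) {
      fs_abort("scenario must be 1..6", "forestseg_configuration_error")
    }
    base_width <- 64L %/% 2L^(scenario - 1L)
  }
  if (is.null(base_width) || base_width < 1L) {
    fs_abort("base_width must be >= 1 (or give a scenario)",
             "forestseg_configuration_error")
  }
  stopifnot(depth >= 1L, in_channels >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  b <- as.integer(base_width)
  enc <- b * 2L^(0:(depth - 1L))
  structure(list(base_width = b, depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 conv_kernel = 3L, up_kernel = 2L,
                 upsample_mode = upsample_mode,
                 dropout_rate = dropout_rate,
                 enc_widths = enc, bridge_width = b * 2L^depth,
                 dec_widths = rev(enc), scenario = scenario),
            class = "unet_spec")
}

#' @rdname unet_spec
#' @export
make_spec <- function(scenario) unet_spec(scenario = scenario)

#' @export
print.unet_spec <- function(x, ...) {
  cat(sprintf(
    "<unet_spec> base %d: encoders (%s), bridge %d, decoders (%s), %s\n",
    x$base_width, paste(x$enc_widths, collapse = ","), x$bridge_width,
    paste(x$dec_widths, collapse = ","), x$upsample_mode))
  invisible(x)
}

#' Total kernel (feature-map) count of a U-Net spec
#'
#' Two convolutions per encoder/bridge/decoder block plus one
#' up-convolution per decoder block; the 1x1 output layer is excluded.
#' For the default depth this is `107 * base_width`.
#'
#' @param spec A [unet_spec()].
#' @return Integer kernel count.
#' @export
count_kernels <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  block_widths <- c(spec$enc_widths, spec$bridge_width, spec$dec_widths)
  as.integer(2L * sum(block_widths) + sum(spec$dec_widths))
}

#' Analytic layer ledger of kernels and trainable parameters
#'
#' Walks the architecture layer by layer and accounts for every weight and
#' bias: a `k x k` convolution from `c_in` to `c_out` channels has
#' `k^2 c_in c_out + c_out` parameters. Decoder blocks start with a 2x2
#' transposed convolution that halves the channels (`4 c (c/2) + c/2`
#' parameters) so that after concatenation with the skip the block input
#' width equals the incoming width; under `plain_upsample` the upsampling
#' is parameter-free and the first decoder convolution sees `c + c/2`
#' channels instead.
#'
#' @param spec A [unet_spec()].
#' @return A `layer_ledger`: data frame with columns `layer`, `kernels`,
#'   `parameters`, plus attributes `total_kernels` and `total_parameters`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  rows <- list()
  add <- function(layer, kernels, parameters) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, kernels = kernels, parameters = parameters)
  }
  conv_params <- function(k, c_in, c_out) k^2 * c_in * c_out + c_out

  c_in <- spec$in_channels
  for (i in seq_along(spec$enc_widths)) {
    w <- spec$enc_widths[i]
    add(sprintf("enc%d_conv1", i), w, conv_params(3, c_in, w))
    add(sprintf("enc%d_conv2", i), w, conv_params(3, w, w))
    c_in <- w
  }
  bw <- spec$bridge_width
  add("bridge_conv1", bw, conv_params(3, c_in, bw))
  add("bridge_conv2", bw, conv_params(3, bw, bw))
  c_cur <- bw
  for (i in seq_along(spec$dec_widths)) {
    w <- spec$dec_widths[i]
    if (spec$upsample_mode == "transposed_halving") {
      add(sprintf("dec%d_upconv", i), w, conv_params(2, c_cur, w))
      conv1_in <- w + w            # upsampled half + skip of equal width
    } else {
      add(sprintf("dec%d_upsample", i), 0L, 0)
      conv1_in <- c_cur + w        # full channels + skip
    }
    add(sprintf("dec%d_conv1", i), w, conv_params(3, conv1_in, w))
    add(sprintf("dec%d_conv2", i), w, conv_params(3, w, w))
    c_cur <- w
  }
  add("output_1x1", 1L, conv_params(1, c_cur, 1))

  ledger <- do.call(rbind, rows)
  attr(ledger, "total_parameters") <- sum(ledger$parameters)
  # kernel total matches count_kernels (output layer excluded there)
  attr(ledger, "total_kernels") <-
    sum(ledger$kernels[ledger$layer != "output_1x1"])
  class(ledger) <- c("layer_ledger", "data.frame")
  ledger
}

#' @export
print.layer_ledger <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("totals: %d kernels (excl. output), %s trainable parameters\n",
              attr(x, "total_kernels"),
              format(attr(x, "total_parameters"), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameters of a spec
#'
#' @param spec A [unet_spec()].
#' @return Numeric parameter total from the [count_parameters()] ledger.
#' @export
total_parameters <- function(spec) {
  attr(count_parameters(spec), "total_parameters")
}

#' Write a layer ledger as CSV
#'
#' @param ledger A `layer_ledger`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}
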