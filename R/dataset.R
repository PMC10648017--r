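# Tiling labeled images into fixed-size training samples and splitting.

#' Cut a labeled image into fixed-size tiles
#'
#' Segmentation networks take square power-of-two inputs, so each labeled
#' image is cut into non-overlapping `tile x tile` patches in row-major
#' order. When an extent is not an exact multiple of the tile size, the
#' trailing partial remainder and the adjacent full tile are both
#' discarded, keeping only tiles clear of the cut edge: a 4,000-pixel
#' extent at tile 128 keeps 3,840 pixels (pixels 3,841-4,000 are
#' dropped), giving 30 x 30 = 900 tiles per image.
#'
#' @param image A [multiband_image()].
#' @param mask Matching `H x W` 0/1 label mask.
#' @param tile Tile side, a power of two `>= 8` (default 128).
#' @param image_id Identifier recorded in each sample's origin.
#' @return List of `tile_sample`s: each has `patch` (`tile x tile x 4` raw
#'   array), `label` (`tile x tile` raw matrix of 0/1), and `origin`
#'   (`image_id`, 0-based `row`, `col` offsets).
#' @export
tile_image <- function(image, mask, tile = 128L, image_id = "image") {
  stopifnot(inherits(image, "multiband_image"))
  tile <- as.integer(tile)
  if (tile < 8L || bitwAnd(tile, tile - 1L) != 0L) {
    fs_abort("tile size must be a power of two >= 8",
             "forestseg_configuration_error")
  }
  mask <- as_binary_mask(mask)
  d <- dim(image$pixels)
  if (!all(dim(mask) == d[1:2])) {
    fs_abort("image and mask shapes differ", "forestseg_input_error")
  }
  raw_mask <- array(as.raw(mask), dim(mask))
  n_axis <- function(extent) {
    n <- extent %/% tile
    if (extent %% tile != 0L) n - 1L else n
  }
  nr <- max(n_axis(d[1]), 0L); nc <- max(n_axis(d[2]), 0L)
  samples <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      r0 <- (i - 1L) * tile; c0 <- (j - 1L) * tile
      samples[[k]] <- structure(
        list(patch = image$pixels[r0 + seq_len(tile), c0 + seq_len(tile), ,
                                  drop = FALSE],
             label = raw_mask[r0 + seq_len(tile), c0 + seq_len(tile),
                              drop = FALSE],
             origin = list(image_id = image_id, row = r0, col = c0)),
        class = "tile_sample")
    }
  }
  samples
}

#' Tile a set of labeled images into one sample list
#'
#' @param images List of [multiband_image()]s — or, for memory-friendly
#'   streaming, a list of zero-argument functions each returning a list
#'   with `image` and `mask` (materialized one at a time).
#' @param masks List of masks aligned with `images` (ignored when
#'   `images` holds generator functions).
#' @param tile Tile side (default 128).
#' @param ids Image identifiers (default `image_001`, ...).
#' @return Concatenated list of `tile_sample`s; every image must have the
#'   same extent.
#' @export
build_dataset <- function(images, masks = NULL, tile = 128L, ids = NULL) {
  n <- length(images)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))
  out <- vector("list", n)
  ref_dim <- NULL
  for (i in seq_len(n)) {
    item <- images[[i]]
    if (is.function(item)) {
      item <- item()
      img <- item$image; msk <- item$mask
    } else {
      img <- item; msk <- masks[[i]]
    }
    d <- dim(img$pixels)
    if (is.null(ref_dim)) {
      ref_dim <- d
    } else if (!all(d == ref_dim)) {
      fs_abort(sprintf(
        "image %d extent %d x %d differs from %d x %d: uniform sizes required",
        i, d[1], d[2], ref_dim[1], ref_dim[2]), "forestseg_input_error")
    }
    out[[i]] <- tile_image(img, msk, tile = tile, image_id = ids[i])
  }
  do.call(c, out)
}

#' Split samples into train / validation / test sets
#'
#' Applies a seeded shuffle, assigns the last `n_test` shuffled samples to
#' the test set, and carves `val_fraction` of the remainder (rounded) into
#' the validation set. The same seed always reproduces the same
#' membership.
#'
#' @param samples List of `tile_sample`s.
#' @param n_test Number of test samples (default 4,400, the convention for
#'   a 14,400-sample corpus, leaving 10,000 for training + validation).
#' @param val_fraction Fraction of the non-test remainder used for
#'   validation (default 0.10).
#' @param seed Integer seed.
#' @return A `dataset_split`: list with `train`, `validation`, `test`
#'   (disjoint sample lists), the index vectors `train_idx` etc., and
#'   `seed`.
#' @export
split_dataset <- function(samples, n_test = 4400L, val_fraction = 0.10,
                          seed = 1L) {
  n <- length(samples)
  if (n_test >= n) {
    fs_abort(sprintf("n_test (%d) must be smaller than the corpus (%d)",
                     n_test, n), "forestseg_configuration_error")
  }
  stopifnot(val_fraction >= 0, val_fraction < 1)
  perm <- with_seed(derive_seed(seed, "split"), sample.int(n))
  test_idx <- if (n_test > 0L) perm[(n - n_test + 1L):n] else integer(0)
  rest <- perm[seq_len(n - n_test)]
  n_val <- round(val_fraction * length(rest))
  val_idx <- if (n_val > 0L) rest[(length(rest) - n_val + 1L):length(rest)]
             else integer(0)
  train_idx <- rest[seq_len(length(rest) - n_val)]
  structure(list(train = samples[train_idx],
                 validation = samples[val_idx],
                 test = samples[test_idx],
                 train_idx = train_idx, val_idx = val_idx,
                 test_idx = test_idx, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d validation / %d test (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Persist a split dataset as NPY arrays plus a CSV manifest
#'
#' Writes `patches.npy` (`n x tile x tile x 4`, 8-bit), `labels.npy`
#' (`n x tile x tile`), and `manifest.csv` (sample id, image id, offsets,
#' split membership) under `dir`.
#'
#' @param split A `dataset_split`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_samples <- c(split$train, split$validation, split$test)
  membership <- rep(c("train", "validation", "test"),
                    c(length(split$train), length(split$validation),
                      length(split$test)))
  n <- length(all_samples)
  tile <- nrow(all_samples[[1]]$label)
  patches <- array(as.raw(0), c(n, tile, tile, 4L))
  labels <- array(as.raw(0), c(n, tile, tile))
  man <- vector("list", n)
  for (i in seq_len(n)) {
    s <- all_samples[[i]]
    patches[i, , , ] <- s$patch
    labels[i, , ] <- s$label
    man[[i]] <- data.frame(sample_id = i, image_id = s$origin$image_id,
                           row = s$origin$row, col = s$origin$col,
                           split = membership[i], stringsAsFactors = FALSE)
  }
  write_npy(patches, file.path(dir, "patches.npy"))
  write_npy(labels, file.path(dir, "labels.npy"))
  utils::write.csv(do.call(rbind, man), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
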