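random_labeled_image <- function(h, w, seed = 1) {
  set.seed(seed)
  img <- multiband_image(array(as.raw(sample(0:255, h * w * 4, TRUE)),
                               c(h, w, 4)))
  mask <- matrix(sample(0:1, h * w, TRUE), h, w)
  list(image = img, mask = mask)
}

test_that("a tile-sized image yields a single identical sample", {
  li <- random_labeled_image(128, 128)
  samples <- tile_image(li$image, li$mask, tile = 128)
  expect_length(samples, 1L)
  expect_identical(samples[[1]]$patch, li$image$pixels)
  expect_identical(array(as.integer(samples[[1]]$label), c(128, 128)),
                   li$mask)
  expect_equal(samples[[1]]$origin$row, 0L)
})

test_that("tiling enumerates row-major offsets and discards remainders", {
  li <- random_labeled_image(256, 256, seed = 2)
  samples <- tile_image(li$image, li$mask, tile = 128)
  expect_length(samples, 4L)
  offs <- t(vapply(samples, function(s) c(s$origin$row, s$origin$col),
                   integer(2)))
  expect_equal(offs, rbind(c(0L, 0L), c(0L, 128L), c(128L, 0L),
                           c(128L, 128L)))

  # non-exact extents drop the partial remainder plus the boundary tile:
  # 4,000 at 128 keeps 30 tiles per side, 416 at 128 keeps 2
  li2 <- random_labeled_image(416, 416, seed = 3)
  expect_length(tile_image(li2$image, li2$mask, tile = 128), 4L)
  offs2 <- vapply(tile_image(li2$image, li2$mask, tile = 128),
                  function(s) s$origin$row, integer(1))
  expect_true(all(offs2 <= 128L))   # pixels 257-416 discarded
  # and an extent below two tiles yields nothing rather than an edge tile
  li3 <- random_labeled_image(200, 200, seed = 8)
  expect_length(tile_image(li3$image, li3$mask, tile = 128), 0L)
})

test_that("tiling then restitching reproduces the cropped image", {
  li <- random_labeled_image(96, 64, seed = 4)
  samples <- tile_image(li$image, li$mask, tile = 32)
  expect_length(samples, 3L * 2L)
  stitched <- array(as.raw(0), c(96, 64, 4))
  for (s in samples) {
    stitched[s$origin$row + 1:32, s$origin$col + 1:32, ] <- s$patch
  }
  expect_identical(stitched, li$image$pixels)
})

test_that("tile preconditions are enforced", {
  li <- random_labeled_image(64, 64)
  expect_error(tile_image(li$image, li$mask, tile = 48),
               class = "forestseg_configuration_error")
  expect_error(tile_image(li$image, li$mask, tile = 4),
               class = "forestseg_configuration_error")
  expect_error(tile_image(li$image, matrix(0L, 32, 32)),
               class = "forestseg_input_error")
})

test_that("build_dataset concatenates uniform images and rejects mixes", {
  li1 <- random_labeled_image(256, 256, seed = 5)
  li2 <- random_labeled_image(256, 256, seed = 6)
  samples <- build_dataset(list(li1$image, li2$image),
                           list(li1$mask, li2$mask), tile = 128)
  expect_length(samples, 8L)
  ids <- unique(vapply(samples, function(s) s$origin$image_id, ""))
  expect_equal(ids, c("image_001", "image_002"))

  li3 <- random_labeled_image(128, 128, seed = 7)
  expect_error(build_dataset(list(li1$image, li3$image),
                             list(li1$mask, li3$mask), tile = 128),
               class = "forestseg_input_error")
})

test_that("build_dataset streams generator functions one at a time", {
  gen <- lapply(1:2, function(i) {
    function() random_labeled_image(128, 128, seed = 10 + i)
  })
  samples <- build_dataset(gen, tile = 64)
  expect_length(samples, 8L)
})

test_that("the split honors the 10,000 / 4,400 convention arithmetic", {
  samples <- as.list(seq_len(14400))    # membership only; payload-agnostic
  split <- split_dataset(samples, n_test = 4400, val_fraction = 0.10,
                         seed = 3)
  expect_length(split$train, 9000L)
  expect_length(split$validation, 1000L)
  expect_length(split$test, 4400L)
})

test_that("splits partition the corpus for every seed", {
  samples <- as.list(seq_len(500))
  for (seed in 1:5) {
    split <- split_dataset(samples, n_test = 100, val_fraction = 0.2,
                           seed = seed)
    all_idx <- c(split$train_idx, split$val_idx, split$test_idx)
    expect_equal(sort(all_idx), 1:500)
  }
})

test_that("splits are deterministic and degenerate cases work", {
  samples <- as.list(seq_len(100))
  s1 <- split_dataset(samples, n_test = 20, seed = 9)
  s2 <- split_dataset(samples, n_test = 20, seed = 9)
  expect_identical(s1$train_idx, s2$train_idx)
  expect_identical(s1$test_idx, s2$test_idx)

  s0 <- split_dataset(samples, n_test = 0, val_fraction = 0, seed = 1)
  expect_length(s0$train, 100L)
  expect_error(split_dataset(samples, n_test = 100),
               class = "forestseg_configuration_error")
})

test_that("datasets persist as NPY pairs plus a manifest", {
  li <- random_labeled_image(128, 128, seed = 20)
  samples <- tile_image(li$image, li$mask, tile = 64)
  split <- split_dataset(samples, n_test = 1, val_fraction = 0.5, seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(split, dir)
  patches <- read_npy(file.path(dir, "patches.npy"))
  labels <- read_npy(file.path(dir, "labels.npy"))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(dim(patches), c(4L, 64L, 64L, 4L))
  expect_equal(dim(labels), c(4L, 64L, 64L))
  expect_equal(nrow(man), 4L)
  expect_equal(sort(unique(man$split)),
               c("test", "train", "validation"))
})
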