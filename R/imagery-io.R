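# Reading, assembling, cutting, and persisting 4-band rasters.

#' Construct a 4-band (RGBN) image
#'
#' The canonical raster container of the package: an `H x W x 4` 8-bit
#' array with fixed band order red, green, blue, near-infrared. Pixels are
#' stored as a raw array (one byte per sample) so that survey-scale rasters
#' stay compact; use [pixel_matrix()] or [pixel_array()] to obtain numeric
#' views.
#'
#' @param pixels `H x W x 4` array of values in `[0, 255]` (numeric,
#'   integer, or raw).
#' @param resolution_m Optional ground-sample distance in meters.
#' @return An object of class `multiband_image`.
#' @export
multiband_image <- function(pixels, resolution_m = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 4L) {
    fs_abort("a multiband image must be an H x W x 4 array",
             "forestseg_format_error")
  }
  if (d[1] < 1L || d[2] < 1L) {
    fs_abort("image height and width must be at least 1",
             "forestseg_dimension_error")
  }
  structure(
    list(pixels = as_raw_raster(pixels),
         band_order = c("R", "G", "B", "NIR"),
         resolution_m = resolution_m),
    class = "multiband_image"
  )
}

#' @export
print.multiband_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multiband_image> %d x %d pixels, bands %s%s\n",
              d[1], d[2], paste(x$band_order, collapse = ","),
              if (is.null(x$resolution_m)) ""
              else sprintf(", %.2g m/px", x$resolution_m)))
  invisible(x)
}

#' @export
dim.multiband_image <- function(x) dim(x$pixels)

#' Numeric views of an image's pixels
#'
#' `pixel_array()` returns the `H x W x 4` raster as a double array;
#' `pixel_matrix()` flattens it to an `(H*W) x 4` matrix (row-major pixel
#' order is irrelevant to the per-pixel models, but the layout is the
#' column-major unravelling of the raster, so `matrix -> raster` round
#' trips are consistent).
#'
#' @param image A [multiband_image()].
#' @return A double array or matrix.
#' @export
pixel_array <- function(image) raw_to_double(image$pixels)

#' @rdname pixel_array
#' @export
pixel_matrix <- function(image) {
  d <- dim(image$pixels)
  matrix(raw_to_double(image$pixels), d[1] * d[2], d[3])
}

#' Assemble an RGBN image from RGB and CIR rasters
#'
#' Airborne surveys often deliver a natural-color (RGB) product and a
#' false-color infrared (CIR) product whose first band is near-infrared.
#' The red and green bands are shared between the two, so a non-redundant
#' 4-band stack is built by keeping all three RGB bands and extracting only
#' the NIR band from the CIR raster.
#'
#' @param rgb `H x W x 3` raster, 8-bit.
#' @param cir `H x W x 3` raster, 8-bit; band `nir_band` is taken as NIR.
#' @param nir_band Which CIR band holds NIR (1-based; default 1).
#' @param resolution_m Optional ground-sample distance, carried through.
#' @return A [multiband_image()] whose bands 1-3 equal `rgb` exactly and
#'   whose band 4 is the selected CIR band.
#' @export
assemble_rgbn <- function(rgb, cir, nir_band = 1L, resolution_m = NULL) {
  dr <- dim(rgb); dc <- dim(cir)
  if (length(dr) != 3L || dr[3] != 3L || length(dc) != 3L || dc[3] != 3L) {
    fs_abort("rgb and cir must both be H x W x 3 rasters",
             "forestseg_format_error")
  }
  if (!all(dr[1:2] == dc[1:2])) {
    fs_abort(sprintf("rgb (%d x %d) and cir (%d x %d) sizes differ",
                     dr[1], dr[2], dc[1], dc[2]),
             "forestseg_dimension_error")
  }
  stopifnot(nir_band >= 1L, nir_band <= 3L)
  rgb <- as_raw_raster(rgb)
  cir <- as_raw_raster(cir)
  out <- array(as.raw(0), c(dr[1], dr[2], 4L))
  out[, , 1:3] <- rgb
  out[, , 4] <- cir[, , nir_band]
  multiband_image(out, resolution_m = resolution_m)
}

#' Cut an image into non-overlapping square regions
#'
#' Splits a large raster into `floor(H/s) * floor(W/s)` square windows of
#' side `s` in row-major order (origin top-left, 0-based offsets, half-open
#' windows). Trailing rows/columns that do not fill a window are discarded,
#' mirroring the tiling convention used downstream.
#'
#' @param image A [multiband_image()].
#' @param region_size Side length of each region, in pixels.
#' @param source_id Identifier recorded on the result.
#' @return A `region_set`: list with `regions` (list of images), `offsets`
#'   (two-column matrix of 0-based row/col origins), `source_id`, and
#'   `region_size`.
#' @export
cut_regions <- function(image, region_size, source_id = "image") {
  stopifnot(inherits(image, "multiband_image"), region_size >= 1L)
  region_size <- as.integer(region_size)
  d <- dim(image$pixels)
  nr <- d[1] %/% region_size
  nc <- d[2] %/% region_size
  if (nr < 1L || nc < 1L) {
    fs_abort(sprintf(
      "region_size %d exceeds image extent %d x %d: no regions",
      region_size, d[1], d[2]), "forestseg_empty_result_error")
  }
  regions <- vector("list", nr * nc)
  offsets <- matrix(0L, nr * nc, 2L,
                    dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      r0 <- (i - 1L) * region_size
      c0 <- (j - 1L) * region_size
      offsets[k, ] <- c(r0, c0)
      regions[[k]] <- multiband_image(
        image$pixels[r0 + seq_len(region_size),
                     c0 + seq_len(region_size), , drop = FALSE],
        resolution_m = image$resolution_m)
    }
  }
  structure(list(regions = regions, offsets = offsets,
                 source_id = source_id, region_size = region_size),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions of %d x %d from '%s'\n",
              length(x$regions), x$region_size, x$region_size, x$source_id))
  invisible(x)
}

#' Read an 8-bit TIFF raster
#'
#' @param path Path to a single- or multi-band 8-bit TIFF.
#' @return An `H x W` or `H x W x C` raw array of values 0-255.
#' @export
read_tiff_raster <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("cannot read TIFF '%s': no such file", path),
             "forestseg_io_error")
  }
  # 4-band rasters are stored as RGBA by convention; libtiff flags the
  # NIR band as an extra sample, which is expected, not an error
  x <- suppressWarnings(tiff::readTIFF(path))   # values scaled to [0, 1]
  as_raw_raster(round(x * 255))
}

#' Write an 8-bit TIFF raster
#'
#' @param x `H x W` or `H x W x C` array (values 0-255) or raw array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_raster <- function(x, path) {
  x <- as_raw_raster(x)
  tiff::writeTIFF(raw_to_double(x) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Persist / restore a raster losslessly
#'
#' `save_array()` writes a raster (or any raw/integer/double array) to NPY
#' or TIFF depending on the file extension; `load_array()` reads it back
#' bit-exactly. A [multiband_image()] is unwrapped to its pixel array.
#'
#' @param x Array, matrix, or [multiband_image()].
#' @param path Destination with extension `.npy`, `.tif`, or `.tiff`.
#' @return `save_array()` returns `path` invisibly; `load_array()` returns
#'   the stored array (raw for 8-bit data).
#' @export
save_array <- function(x, path) {
  if (inherits(x, "multiband_image")) x <- x$pixels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    npy = write_npy(x, path),
    tif = ,
    tiff = write_tiff_raster(x, path),
    fs_abort(sprintf("unsupported array extension '.%s' in '%s'", ext, path),
             "forestseg_io_error")
  )
  invisible(path)
}

#' @rdname save_array
#' @export
load_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    npy = read_npy(path),
    tif = ,
    tiff = read_tiff_raster(path),
    fs_abort(sprintf("unsupported array extension '.%s' in '%s'", ext, path),
             "forestseg_io_error")
  )
}

#' Colors used when rendering forest masks
#'
#' Forest pixels render as forest green `(34, 139, 34)`, everything else as
#' black `(0, 0, 0)`.
#' @export
FOREST_COLOR <- c(34L, 139L, 34L)

#' @rdname FOREST_COLOR
#' @export
NONFOREST_COLOR <- c(0L, 0L, 0L)

#' Export a binary forest mask as a colored 3-band TIFF
#'
#' @param mask `H x W` 0/1 matrix (1 = forest).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  mask <- as_binary_mask(mask)
  d <- dim(mask)
  out <- array(0L, c(d[1], d[2], 3L))
  for (b in 1:3) {
    out[, , b] <- ifelse(mask == 1L, FOREST_COLOR[b], NONFOREST_COLOR[b])
  }
  write_tiff_raster(out, path)
}

# Coerce to a validated 0/1 integer matrix.
as_binary_mask <- function(mask) {
  if (is.raw(mask)) mask <- raw_to_int(mask)
  m <- as.matrix(mask)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) {
    fs_abort("mask values must be 0 or 1", "forestseg_format_error")
  }
  m
}
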