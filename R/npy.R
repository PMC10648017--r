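# Minimal reader/writer for the NumPy .npy array format (version 1.0,
# little-endian). Supports the dtypes this package produces: |u1 (8-bit
# rasters), <i4 and <i8 (integer), <f8 (double). Arrays are written in
# C order, matching what numpy.save produces by default.

npy_magic <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

#' Write an array in NumPy .npy format
#'
#' @param x An atomic array, matrix, or vector (raw, integer, or double).
#'   Raw data are written as unsigned 8-bit (`|u1`), integers as `<i4`,
#'   doubles as `<f8`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  if (is.raw(x)) {
    descr <- "|u1"
  } else if (is.integer(x)) {
    descr <- "<i4"
  } else if (is.double(x)) {
    descr <- "<f8"
  } else {
    fs_abort("write_npy supports raw, integer, and double arrays",
             "forestseg_format_error")
  }
  shape <- if (length(dims) == 1L) {
    sprintf("(%d,)", dims)
  } else {
    sprintf("(%s)", paste(dims, collapse = ", "))
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  # total header block (magic 6 + version 2 + len 2 + dict) padded to 64
  unpadded <- 10L + nchar(header) + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")

  # C order: last index varies fastest -> reverse-permute the column-major
  # array before flattening.
  if (length(dims) > 1L) {
    x <- aperm(array(x, dims), rev(seq_along(dims)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  if (is.raw(x)) {
    writeBin(as.vector(x), con)
  } else if (is.integer(x)) {
    writeBin(as.vector(x), con, size = 4L, endian = "little")
  } else {
    writeBin(as.vector(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NumPy .npy file
#'
#' @param path Path to a `.npy` file holding a `|u1`, `<i1`, `<i4`, `<f4`,
#'   or `<f8` array.
#' @return An array with the file's shape; `|u1` data come back as a raw
#'   array, integer dtypes as integer, floats as double.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("cannot read NPY file '%s': no such file", path),
             "forestseg_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, npy_magic)) {
    fs_abort(sprintf("'%s' is not an NPY file (bad magic)", path),
             "forestseg_io_error")
  }
  version <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(version[1]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  }
  header <- readChar(con, hlen, useBytes = TRUE)

  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  n <- if (length(dims)) prod(dims) else 1L

  data <- switch(descr,
    "|u1" = readBin(con, "raw", n),
    "<i1" = readBin(con, "integer", n, size = 1L),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    fs_abort(sprintf("unsupported NPY dtype '%s' in '%s'", descr, path),
             "forestseg_io_error")
  )
  if (length(dims) <= 1L) {
    return(data)
  }
  if (fortran) {
    array(data, dims)
  } else {
    aperm(array(data, rev(dims)), rev(seq_along(dims)))
  }
}
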