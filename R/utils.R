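#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers can distinguish error families
# (dimension, format, configuration, ...).
fs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "forestseg_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Derive a stage-specific random seed from a master seed
#'
#' One master seed drives a whole run; every stochastic stage draws its own
#' seed through this deterministic hash so stages can be re-run in isolation
#' and still reproduce. The result is always a positive 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"gmm"`, `"split"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Raw <-> numeric helpers. Rasters are held as raw arrays (one byte per
# sample, values 0..255) so survey-scale images stay memory-friendly.
as_raw_raster <- function(x) {
  if (is.raw(x)) return(x)
  v <- as.vector(x)
  if (anyNA(v) || any(v < 0) || any(v > 255)) {
    fs_abort("raster values must lie in [0, 255]", "forestseg_format_error")
  }
  r <- as.raw(round(v))
  dim(r) <- dim(x)
  r
}

raw_to_int <- function(x) {
  v <- as.integer(x)
  dim(v) <- dim(x)
  v
}

raw_to_double <- function(x) {
  v <- as.double(as.integer(x))
  dim(v) <- dim(x)
  v
}
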