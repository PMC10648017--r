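# Synthetic 4-band aerial scenes with known ground truth.
#
# The generator emulates the statistical structure the labeling pipeline
# assumes in real survey imagery: contiguous land-cover patches, per-class
# 4-band Gaussian pixel distributions, forest split into a bright-NIR lit
# canopy and a dark shadow subpopulation, small withered-tree holes inside
# forest regions, and additive sensor noise clipped to 8-bit range.

#' Describe one land-cover class of a synthetic scene
#'
#' @param name Class name.
#' @param mean Length-4 numeric (R, G, B, NIR), each in `[0, 255]`.
#' @param cov 4x4 symmetric positive-definite covariance. A scalar is
#'   expanded to `diag(cov, 4)` (isotropic spread).
#' @param is_forest Whether the class is the forest (positive) class.
#' @param subpopulations Optional list of sub-classes, each a list with
#'   `mean`, `cov`, and `weight`; weights must sum to 1. Used to model
#'   forest as lit canopy + shadow.
#' @param proportion Relative share of the scene layout given to the class.
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, mean, cov, is_forest = FALSE,
                       subpopulations = NULL, proportion = 1) {
  if (length(cov) == 1L) cov <- diag(as.numeric(cov), 4L)
  check_mvn_params(mean, cov, name)
  if (!is.null(subpopulations)) {
    w <- vapply(subpopulations, function(s) s$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-9) {
      fs_abort(sprintf("subpopulation weights of '%s' must sum to 1", name),
               "forestseg_specification_error")
    }
    for (s in subpopulations) {
      if (length(s$cov) == 1L) s$cov <- diag(as.numeric(s$cov), 4L)
      check_mvn_params(s$mean, s$cov, paste0(name, " subpopulation"))
    }
    subpopulations <- lapply(subpopulations, function(s) {
      if (length(s$cov) == 1L) s$cov <- diag(as.numeric(s$cov), 4L)
      s
    })
  }
  structure(list(name = name, mean = as.numeric(mean), cov = cov,
                 is_forest = isTRUE(is_forest),
                 subpopulations = subpopulations,
                 proportion = proportion),
            class = "class_spec")
}

check_mvn_params <- function(mean, cov, what) {
  if (length(mean) != 4L || any(mean < 0) || any(mean > 255)) {
    fs_abort(sprintf("'%s': mean must be 4 values in [0, 255]", what),
             "forestseg_specification_error")
  }
  if (!isTRUE(all.equal(cov, t(cov))) ||
      inherits(try(chol(cov), silent = TRUE), "try-error")) {
    fs_abort(sprintf(
      "'%s': covariance must be symmetric positive-definite", what),
      "forestseg_specification_error")
  }
  invisible(TRUE)
}

#' Describe a synthetic scene
#'
#' @param size Scene side length in pixels (>= 32).
#' @param classes List of [class_spec()]s; at least two, exactly one with
#'   `is_forest = TRUE`.
#' @param forest_shadow_fraction Fraction of forest pixels drawn from the
#'   shadow subpopulation (spatially contiguous patches), in `[0, 1]`.
#' @param hole_rate Expected withered-tree holes per 1,000 forest pixels.
#' @param noise_sd Standard deviation of additive per-band sensor noise
#'   (8-bit levels).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param layout `"blobs"` (smoothed random field, contiguous patches;
#'   default) or `"voronoi"` (polygonal patches).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size, classes, forest_shadow_fraction = 0.35,
                       hole_rate = 0.3, noise_sd = 5, seed = 1L,
                       layout = c("blobs", "voronoi")) {
  layout <- match.arg(layout)
  if (size < 32L) {
    fs_abort("scene size must be at least 32 pixels",
             "forestseg_specification_error")
  }
  if (length(classes) < 2L) {
    fs_abort("a scene needs at least two classes",
             "forestseg_specification_error")
  }
  if (sum(vapply(classes, function(cl) cl$is_forest, logical(1))) != 1L) {
    fs_abort("exactly one class must have is_forest = TRUE",
             "forestseg_specification_error")
  }
  stopifnot(forest_shadow_fraction >= 0, forest_shadow_fraction <= 1,
            hole_rate >= 0, noise_sd >= 0)
  structure(list(size = as.integer(size), classes = classes,
                 forest_shadow_fraction = forest_shadow_fraction,
                 hole_rate = hole_rate, noise_sd = noise_sd,
                 seed = as.integer(seed), layout = layout),
            class = "scene_spec")
}

#' Default five-class scene
#'
#' Emulates the land covers typical of temperate survey imagery: forest,
#' orchard, crops, bare land, and settlement. Forest is modeled as two
#' subpopulations — lit canopy, whose NIR mean is strictly the highest of
#' all classes (dense healthy vegetation reflects strongly in NIR), and
#' tree shadow, elementwise darker. The numeric class statistics are
#' package defaults chosen to make the classes spectrally separable at
#' realistic 8-bit levels; they are documented in the methods vignette.
#'
#' @param size Scene side length in pixels.
#' @param ... Passed on to [scene_spec()] (e.g. `seed`, `noise_sd`).
#' @return A `scene_spec`.
#' @export
default_scene_spec <- function(size, ...) {
  lit    <- list(mean = c(45, 90, 50, 200), cov = diag(64, 4), weight = 1)
  shadow <- list(mean = c(18, 32, 20, 90),  cov = diag(36, 4), weight = 1)
  classes <- list(
    class_spec("forest", lit$mean, lit$cov, is_forest = TRUE,
               subpopulations = list(
                 list(mean = lit$mean, cov = lit$cov, weight = 0.65),
                 list(mean = shadow$mean, cov = shadow$cov, weight = 0.35)),
               proportion = 0.40),
    class_spec("orchard",    c(97, 122, 70, 134), diag(100, 4),
               proportion = 0.12),
    class_spec("crops",      c(105, 130, 75, 128), diag(144, 4),
               proportion = 0.20),
    class_spec("bare_land",  c(150, 132, 112, 58), diag(144, 4),
               proportion = 0.16),
    class_spec("settlement", c(160, 146, 126, 50), diag(196, 4),
               proportion = 0.12))
  scene_spec(size, classes, ...)
}

#' Minimal well-separated k-class spec
#'
#' Convenience spec used in model-selection studies: `k` spectrally
#' well-separated classes with no shadow subpopulation and no holes, the
#' first class being forest.
#'
#' @param size Scene side in pixels.
#' @param k Number of classes (2 to 5).
#' @param ... Passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
separable_scene_spec <- function(size, k = 4, ...) {
  stopifnot(k >= 2L, k <= 5L)
  full <- list(
    class_spec("forest",     c(53, 87, 59, 200),   diag(49, 4),
               is_forest = TRUE, proportion = 0.3),
    class_spec("crops",      c(129, 159, 80, 149), diag(49, 4),
               proportion = 0.25),
    class_spec("bare_land",  c(151, 118, 124, 45), diag(49, 4),
               proportion = 0.25),
    class_spec("settlement", c(170, 202, 207, 59), diag(49, 4),
               proportion = 0.2),
    class_spec("water",      c(20, 40, 80, 10),    diag(25, 4),
               proportion = 0.15))
  scene_spec(size, full[seq_len(k)], forest_shadow_fraction = 0,
             hole_rate = 0, ...)
}

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_dim1 <- function(x) {
    n <- nrow(x)
    padded <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (o in seq_along(k)) {
      out <- out + k[o] * padded[(o - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth_dim1(t(smooth_dim1(m))))
}

# Partition a size x size grid into class ids with (near-)exact proportions.
scene_layout <- function(size, props, layout) {
  n <- size * size
  cum <- cumsum(props) / sum(props)
  if (layout == "blobs") {
    field <- gaussian_smooth(matrix(stats::rnorm(n), size, size),
                             sigma = size / 12)
    # rank-threshold: exact class proportions, contiguous level bands
    rk <- rank(field, ties.method = "first")
    breaks <- c(0, round(cum * n))
    cls <- findInterval(rk, breaks, left.open = TRUE)
  } else {
    n_sites <- max(length(props) * 6L, 30L)
    sites <- cbind(stats::runif(n_sites, 1, size),
                   stats::runif(n_sites, 1, size))
    site_cls <- findInterval(stats::runif(n_sites), c(0, cum),
                             left.open = TRUE)
    # guarantee every class owns at least one site
    site_cls[seq_along(props)] <- seq_along(props)
    gr <- expand.grid(row = seq_len(size), col = seq_len(size))
    d2 <- outer(gr$row, sites[, 1], "-")^2 + outer(gr$col, sites[, 2], "-")^2
    cls <- site_cls[max.col(-d2, ties.method = "first")]
  }
  matrix(as.integer(cls), size, size)
}

# Place disk-shaped holes (radius 1-3) at random forest pixels.
punch_holes <- function(class_map, forest_id, hole_class, hole_rate) {
  forest_idx <- which(class_map == forest_id)
  if (!length(forest_idx) || hole_rate <= 0) return(class_map)
  n_holes <- stats::rpois(1, hole_rate * length(forest_idx) / 1000)
  if (n_holes == 0L) return(class_map)
  size_r <- nrow(class_map); size_c <- ncol(class_map)
  centers <- sample(forest_idx, min(n_holes, length(forest_idx)))
  radii <- sample(1:3, length(centers), replace = TRUE)
  for (h in seq_along(centers)) {
    ci <- (centers[h] - 1L) %% size_r + 1L
    cj <- (centers[h] - 1L) %/% size_r + 1L
    r <- radii[h]
    ii <- max(1L, ci - r):min(size_r, ci + r)
    jj <- max(1L, cj - r):min(size_c, cj + r)
    for (i in ii) for (j in jj) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2 && class_map[i, j] == forest_id) {
        class_map[i, j] <- hole_class
      }
    }
  }
  class_map
}

#' Generate a synthetic scene and its ground truth
#'
#' Draws a seeded land-cover layout, assigns every pixel a 4-band value
#' from its class (or forest subpopulation) Gaussian, adds sensor noise,
#' and clips to `[0, 255]`. Identical specs (including seed) give
#' bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (a [multiband_image()]) and `truth` (class
#'   `ground_truth`: `mask` 0/1 forest matrix, `class_map` integer class
#'   ids, `shadow` 0/1 matrix of shadow-subpopulation forest pixels).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    size <- spec$size
    props <- vapply(spec$classes, function(cl) cl$proportion, numeric(1))
    class_map <- scene_layout(size, props, spec$layout)
    forest_id <- which(vapply(spec$classes, function(cl) cl$is_forest,
                              logical(1)))
    nonforest <- setdiff(seq_along(spec$classes), forest_id)
    hole_class <- {
      bare <- grep("bare", vapply(spec$classes, `[[`, "", "name"))
      if (length(bare)) bare[1] else nonforest[1]
    }
    class_map <- punch_holes(class_map, forest_id, hole_class,
                             spec$hole_rate)
    mask <- matrix(as.integer(class_map == forest_id), size, size)

    # contiguous shadow patches: threshold a second smoothed field at the
    # requested fraction of forest pixels
    shadow <- matrix(0L, size, size)
    if (spec$forest_shadow_fraction > 0 && any(mask == 1L)) {
      sfield <- gaussian_smooth(matrix(stats::rnorm(size * size), size, size),
                                sigma = size / 24)
      fvals <- sfield[mask == 1L]
      thr <- stats::quantile(fvals, spec$forest_shadow_fraction,
                             names = FALSE, type = 1)
      shadow[mask == 1L & sfield <= thr] <- 1L
    }

    vals <- matrix(0, size * size, 4L)
    for (ci in seq_along(spec$classes)) {
      cl <- spec$classes[[ci]]
      if (cl$is_forest && spec$forest_shadow_fraction > 0 &&
          !is.null(cl$subpopulations) && length(cl$subpopulations) >= 2L) {
        lit_idx <- which(class_map == ci & shadow == 0L)
        sh_idx <- which(class_map == ci & shadow == 1L)
        vals[lit_idx, ] <- draw_mvn(length(lit_idx),
                                    cl$subpopulations[[1]]$mean,
                                    cl$subpopulations[[1]]$cov)
        vals[sh_idx, ] <- draw_mvn(length(sh_idx),
                                   cl$subpopulations[[2]]$mean,
                                   cl$subpopulations[[2]]$cov)
      } else {
        idx <- which(class_map == ci)
        vals[idx, ] <- draw_mvn(length(idx), cl$mean, cl$cov)
      }
    }
    if (spec$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), sd = spec$noise_sd)
    }
    vals <- pmin(pmax(round(vals), 0), 255)
    image <- multiband_image(array(as.raw(vals), c(size, size, 4L)))
    truth <- structure(list(mask = mask, class_map = class_map,
                            shadow = shadow),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

draw_mvn <- function(n, mean, cov) {
  if (n == 0L) return(matrix(0, 0L, 4L))
  z <- matrix(stats::rnorm(n * 4L), n, 4L)
  sweep(z %*% chol(cov), 2L, mean, "+")
}

#' Serialize / restore a scene spec as YAML
#'
#' @param spec A [scene_spec()].
#' @param path YAML file path.
#' @return `write_scene_spec()` returns `path` invisibly;
#'   `read_scene_spec()` returns the restored `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  obj <- list(size = spec$size,
              forest_shadow_fraction = spec$forest_shadow_fraction,
              hole_rate = spec$hole_rate, noise_sd = spec$noise_sd,
              seed = spec$seed, layout = spec$layout,
              classes = lapply(spec$classes, function(cl) {
                list(name = cl$name, mean = cl$mean,
                     cov = as.vector(cl$cov), is_forest = cl$is_forest,
                     proportion = cl$proportion,
                     subpopulations = lapply(cl$subpopulations, function(s) {
                       list(mean = s$mean, cov = as.vector(s$cov),
                            weight = s$weight)
                     }))
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  classes <- lapply(obj$classes, function(cl) {
    subs <- cl$subpopulations
    if (!is.null(subs) && length(subs)) {
      subs <- lapply(subs, function(s) {
        list(mean = as.numeric(s$mean),
             cov = matrix(as.numeric(s$cov), 4L, 4L), weight = s$weight)
      })
    } else {
      subs <- NULL
    }
    class_spec(cl$name, as.numeric(cl$mean),
               matrix(as.numeric(cl$cov), 4L, 4L),
               is_forest = isTRUE(cl$is_forest), subpopulations = subs,
               proportion = cl$proportion)
  })
  scene_spec(obj$size, classes,
             forest_shadow_fraction = obj$forest_shadow_fraction,
             hole_rate = obj$hole_rate, noise_sd = obj$noise_sd,
             seed = obj$seed, layout = obj$layout)
}
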