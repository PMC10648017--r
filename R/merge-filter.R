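# Collapsing GMM clusters into a forest/no-forest mask and cleaning it.

#' Derive a forest merge rule from a fitted model and its cluster map
#'
#' Forest canopies are not spectrally uniform: tree shadows form a darker
#' cluster interleaved with the bright-NIR lit canopy, so a single mixture
#' component rarely covers the forest. The automatic rule formalizes the
#' visual merge: the component with the highest NIR mean seeds the forest
#' set; every other component joins it when it is (a) spatially interleaved
#' with the seed — its 4-neighborhood adjacency score
#' `A(i) = #{pixel pairs between i and seed} / #{pixels in i}` reaches
#' `adjacency_threshold` — and (b) darker than the seed in visible
#' luminance (mean of the R, G, B means), the shadow criterion.
#'
#' @param model A fitted `gmm_model` (`K >= 2`).
#' @param cmap A `cluster_map` from [predict_clusters()].
#' @param adjacency_threshold Minimum adjacency score, default 0.10.
#' @return A `merge_rule`: list with `forest_components` (0-based indices),
#'   `rationale` (`"auto"`), `seed_component`, and the per-component
#'   `adjacency` scores.
#' @export
auto_merge_rule <- function(model, cmap, adjacency_threshold = 0.10) {
  if (model$K < 2L) {
    fs_abort("auto merge needs at least two components",
             "forestseg_rule_error")
  }
  seed_comp <- which.max(model$means[, 4L]) - 1L
  counts <- tabulate(as.vector(cmap) + 1L, nbins = model$K)
  if (counts[seed_comp + 1L] == 0L) {
    fs_abort("the highest-NIR component has no pixels in the map",
             "forestseg_rule_error")
  }
  lum <- rowMeans(model$means[, 1:3, drop = FALSE])
  adjacency <- numeric(model$K)
  # 4-neighborhood pair counts against the seed component, per component
  pair_counts <- numeric(model$K)
  tally <- function(a_lab, b_seed) {
    sel <- b_seed & !is.na(a_lab)
    if (any(sel)) {
      t0 <- tabulate(a_lab[sel] + 1L, nbins = model$K)
      pair_counts <<- pair_counts + t0
    }
  }
  H <- nrow(cmap); W <- ncol(cmap)
  # vertical neighbors
  a <- cmap[-H, , drop = FALSE]; b <- cmap[-1L, , drop = FALSE]
  tally(a, b == seed_comp)
  tally(b, a == seed_comp)
  # horizontal neighbors
  a <- cmap[, -W, drop = FALSE]; b <- cmap[, -1L, drop = FALSE]
  tally(a, b == seed_comp)
  tally(b, a == seed_comp)
  nz <- counts > 0L
  adjacency[nz] <- pair_counts[nz] / counts[nz]
  adjacency[seed_comp + 1L] <- NA_real_

  included <- which(adjacency >= adjacency_threshold &
                      lum < lum[seed_comp + 1L]) - 1L
  structure(list(forest_components = sort(c(seed_comp, included)),
                 rationale = "auto", seed_component = seed_comp,
                 adjacency = adjacency,
                 adjacency_threshold = adjacency_threshold),
            class = "merge_rule")
}

#' Manually specify the forest components
#'
#' @param components 0-based component indices to merge into the forest
#'   class.
#' @return A `merge_rule` with rationale `"manual"`.
#' @export
manual_merge_rule <- function(components) {
  if (!length(components)) {
    fs_abort("a merge rule needs at least one component",
             "forestseg_rule_error")
  }
  structure(list(forest_components = sort(as.integer(components)),
                 rationale = "manual"),
            class = "merge_rule")
}

#' Collapse a cluster map into a binary forest mask
#'
#' @param cmap A `cluster_map` (0-based labels).
#' @param rule A `merge_rule`.
#' @return `H x W` integer 0/1 matrix (1 = forest), class `binary_mask`.
#' @export
apply_merge <- function(cmap, rule) {
  K <- attr(cmap, "K")
  comp <- rule$forest_components
  if (!is.null(K)) {
    if (any(comp < 0L | comp >= K)) {
      fs_abort("merge rule references components outside [0, K)",
               "forestseg_rule_error")
    }
    if (length(comp) >= K) {
      warning("merge rule covers every component: mask is all forest")
    }
  }
  m <- matrix(as.integer(matrix(cmap, nrow(cmap), ncol(cmap)) %in% comp),
              nrow(cmap), ncol(cmap))
  structure(m, class = c("binary_mask", "matrix"))
}

# Windowed sum with edge-replication padding, via integral images.
box_sum_replicate <- function(m, w) {
  r <- (w - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  padded <- m[c(rep(1L, r), seq_len(H), rep(H, r)),
              c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  # integral image with a leading zero row/col
  s <- matrix(0, H + 2L * r + 1L, W + 2L * r + 1L)
  s[-1L, -1L] <- apply(apply(padded, 2L, cumsum), 1L, cumsum) |> t()
  i2 <- (w + 1L):(H + w); i1 <- 1L:H
  j2 <- (w + 1L):(W + w); j1 <- 1L:W
  s[i2, j2] - s[i1, j2] - s[i2, j1] + s[i1, j1]
}

#' Clean a binary mask with a median filter then a morphological closing
#'
#' The median filter (square window, edge-replication padding) removes
#' salt-and-pepper artifacts; the closing — dilation then erosion with the
#' same square structuring element, forest as foreground — fills the small
#' voids that withered or deciduous trees leave inside forest areas. The
#' default 9 x 9 kernels reflect the 9-pixel filtering convention; pass
#' `median_size = 3` for the 3 x 3 (= 9 pixels) reading.
#'
#' @param mask A 0/1 `binary_mask` (or plain matrix).
#' @param median_size Odd median window side, default 9.
#' @param closing_size Odd structuring-element side, default 9.
#' @return The filtered `binary_mask`.
#' @export
postprocess_mask <- function(mask, median_size = 9L, closing_size = 9L) {
  if (median_size %% 2L != 1L || closing_size %% 2L != 1L ||
      median_size < 1L || closing_size < 1L) {
    fs_abort("filter kernel sizes must be odd and >= 1",
             "forestseg_configuration_error")
  }
  m <- as_binary_mask(mask)
  if (median_size > 1L) {
    s <- box_sum_replicate(m, median_size)
    m <- matrix(as.integer(s * 2L > median_size^2), nrow(m), ncol(m))
  }
  if (closing_size > 1L) {
    s <- box_sum_replicate(m, closing_size)
    dil <- matrix(as.integer(s > 0), nrow(m), ncol(m))
    s <- box_sum_replicate(dil, closing_size)
    m <- matrix(as.integer(s == closing_size^2), nrow(m), ncol(m))
  }
  structure(m, class = c("binary_mask", "matrix"))
}

#' Davies-Bouldin cluster-validity index of a labeling
#'
#' With class centers `c_i` (per-band means) and dispersions `sigma_i`
#' (mean Euclidean distance of class-`i` pixels to `c_i`), the index is
#' `mean_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`; for the
#' two-class forest/no-forest case this reduces to
#' `(sigma_0 + sigma_1) / d(c_0, c_1)`. Lower is better: compact,
#' well-separated classes score low. The index is invariant to uniform
#' positive rescaling of the pixel values and to relabeling.
#'
#' @param pixels `N x d` matrix (or [multiband_image()]) of pixel spectra.
#' @param mask Class labels per pixel: a `binary_mask`, or any vector /
#'   matrix of labels aligned with `pixels` rows.
#' @return The (non-negative) index.
#' @export
davies_bouldin <- function(pixels, mask) {
  if (inherits(pixels, "multiband_image")) pixels <- pixel_matrix(pixels)
  pixels <- as.matrix(pixels)
  lab <- as.vector(mask)
  stopifnot(length(lab) == nrow(pixels))
  classes <- sort(unique(lab))
  if (length(classes) < 2L) {
    fs_abort("Davies-Bouldin needs at least two non-empty classes",
             "forestseg_validity_error")
  }
  k <- length(classes)
  centers <- matrix(0, k, ncol(pixels))
  sigma <- numeric(k)
  for (i in seq_len(k)) {
    px <- pixels[lab == classes[i], , drop = FALSE]
    centers[i, ] <- colMeans(px)
    sigma[i] <- mean(sqrt(rowSums(sweep(px, 2L, centers[i, ])^2)))
  }
  ratio <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        dij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
        ratio[i, j] <- (sigma[i] + sigma[j]) / dij
      }
    }
  }
  mean(apply(ratio, 1L, max, na.rm = TRUE))
}

#' Rank labeled images by cluster validity and select the best
#'
#' Computes the Davies-Bouldin index of every (image, mask) pair, orders
#' ascending (ties broken by image id), and selects the `top_n` best.
#' Pairs whose mask has an empty class are excluded with a logged reason.
#'
#' @param items Named list; each element a list with `image` (a
#'   [multiband_image()]) and `mask` (a `binary_mask`). Names are the
#'   image ids (defaults to positional ids).
#' @param top_n How many images to select (default 16).
#' @return A `db_ranking`: list with `ranking` (data frame `image_id`,
#'   `db_index`, `selected`, ascending), `selected_ids`, and `excluded`
#'   (data frame `image_id`, `reason`).
#' @export
rank_and_select <- function(items, top_n = 16L) {
  ids <- names(items)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(items))
  scores <- rep(NA_real_, length(items))
  reasons <- character(0); excluded_ids <- character(0)
  for (i in seq_along(items)) {
    res <- tryCatch(
      davies_bouldin(items[[i]]$image, items[[i]]$mask),
      forestseg_validity_error = function(e) e)
    if (inherits(res, "condition")) {
      excluded_ids <- c(excluded_ids, ids[i])
      reasons <- c(reasons, conditionMessage(res))
    } else {
      scores[i] <- res
    }
  }
  valid <- which(is.finite(scores))
  if (length(valid) < top_n) {
    fs_abort(sprintf(
      "only %d of %d images are rankable but top_n=%d (excluded: %s)",
      length(valid), length(items), top_n,
      paste(excluded_ids, collapse = ", ")),
      "forestseg_selection_error")
  }
  ord <- valid[order(scores[valid], ids[valid])]
  ranking <- data.frame(image_id = ids[ord], db_index = scores[ord],
                        selected = seq_along(ord) <= top_n,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 selected_ids = ranking$image_id[ranking$selected],
                 excluded = data.frame(image_id = excluded_ids,
                                       reason = reasons,
                                       stringsAsFactors = FALSE)),
            class = "db_ranking")
}

#' Write a criterion scan or ranking as CSV
#'
#' @param x A `criterion_scan` or `db_ranking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("K", "logL", "k", "AIC", "BIC")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_ranking_csv <- function(x, path) {
  utils::write.csv(x$ranking, path, row.names = FALSE)
  invisible(path)
}
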