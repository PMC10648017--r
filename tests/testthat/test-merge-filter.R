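# Fixture model: component 0 = lit forest (bright NIR), component 1 =
# shadow (dark), component 2 = bright non-forest.
fixture_model <- function(K = 2) {
  means <- rbind(c(50, 90, 60, 200),     # lit forest: NIR seed
                 c(20, 30, 20, 90),      # shadow: darker
                 c(160, 140, 120, 50))   # bright cover
  structure(list(K = as.integer(K), weights = rep(1 / K, K),
                 means = means[seq_len(K), , drop = FALSE],
                 covariances = rep(list(diag(25, 4)), K),
                 covariance_type = "full", seed = 1L, converged = TRUE,
                 loglik_trace = 0, ridge_applied = FALSE),
            class = "gmm_model")
}

as_cmap <- function(m, K) structure(m, K = K, class = c("cluster_map",
                                                        "matrix"))

test_that("interleaved lit/shadow clusters are merged", {
  # checkerboard of components 0 and 1: every shadow pixel touches the seed
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2L)
  rule <- auto_merge_rule(fixture_model(2), as_cmap(cb, 2L))
  expect_equal(rule$forest_components, c(0L, 1L))
  expect_equal(rule$seed_component, 0L)
  expect_gte(rule$adjacency[2], 1)    # A(shadow) is ~4 on a checkerboard
  expect_equal(rule$rationale, "auto")
})

test_that("a distant dark cluster with little shared boundary is excluded", {
  # left half component 0, right half component 1: only one shared column
  halves <- cbind(matrix(0L, 20, 10), matrix(1L, 20, 10))
  rule <- auto_merge_rule(fixture_model(2), as_cmap(halves, 2L))
  # adjacency = 20 boundary pairs / 200 pixels = 0.10 at the threshold;
  # widen the halves to push it below
  wide <- cbind(matrix(0L, 20, 15), matrix(1L, 20, 15))
  rule_wide <- auto_merge_rule(fixture_model(2), as_cmap(wide, 2L))
  expect_equal(rule_wide$forest_components, 0L)
  expect_lt(rule_wide$adjacency[2], 0.10)
})

test_that("brighter clusters never merge into the forest", {
  # checkerboard of seed and the BRIGHT component: adjacency is high but
  # the luminance veto holds
  cb <- outer(1:8, 1:8, function(i, j) 2L * ((i + j) %% 2L))
  rule <- auto_merge_rule(fixture_model(3), as_cmap(cb, 3L))
  expect_equal(rule$forest_components, 0L)
})

test_that("manual merge rules pass through verbatim", {
  rule <- manual_merge_rule(c(0, 2))
  expect_equal(rule$forest_components, c(0L, 2L))
  expect_equal(rule$rationale, "manual")
  expect_error(manual_merge_rule(integer(0)),
               class = "forestseg_rule_error")
})

test_that("apply_merge maps labels to the binary mask", {
  cmap <- as_cmap(matrix(c(0L, 1L, 2L, 1L), 2, 2), 3L)
  mask <- apply_merge(cmap, manual_merge_rule(c(0, 2)))
  expect_equal(matrix(mask, 2, 2), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  # counting identity
  expect_equal(sum(mask), sum(cmap == 0L) + sum(cmap == 2L))
  # all components -> all ones, with a warning
  expect_warning(all1 <- apply_merge(cmap, manual_merge_rule(0:2)))
  expect_true(all(all1 == 1L))
  # rule = {0} on a map of zeros -> all ones
  zeros <- as_cmap(matrix(0L, 3, 3), 1L)
  expect_warning(m0 <- apply_merge(zeros, manual_merge_rule(0L)))
  expect_true(all(m0 == 1L))
  expect_error(apply_merge(cmap, manual_merge_rule(5L)),
               class = "forestseg_rule_error")
})

test_that("postprocess leaves constant masks unchanged", {
  ones <- matrix(1L, 20, 20)
  expect_true(all(postprocess_mask(ones) == 1L))
  zeros <- matrix(0L, 20, 20)
  expect_true(all(postprocess_mask(zeros) == 0L))
})

test_that("the median filter removes an isolated forest pixel", {
  m <- matrix(0L, 21, 21)
  m[11, 11] <- 1L
  out <- postprocess_mask(m, median_size = 9, closing_size = 1)
  expect_true(all(out == 0L))
})

test_that("closing fills a small hole inside a forest block", {
  m <- matrix(1L, 31, 31)
  m[15:17, 15:17] <- 0L                       # 3x3 hole
  out <- postprocess_mask(m, median_size = 1, closing_size = 9)
  expect_true(all(out == 1L))
})

test_that("even filter kernels are rejected", {
  expect_error(postprocess_mask(matrix(1L, 4, 4), median_size = 8),
               class = "forestseg_configuration_error")
  expect_error(postprocess_mask(matrix(1L, 4, 4), closing_size = 2),
               class = "forestseg_configuration_error")
})

test_that("Davies-Bouldin matches hand-computed two-cluster cases", {
  # zero-dispersion point clusters at distance 5
  px <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(5, 0, 0, 0), c(5, 0, 0, 0))
  expect_equal(davies_bouldin(px, c(0, 0, 1, 1)), 0)
  # class 0 = {0, 2}, class 1 = {10, 12} on the first band:
  # sigma = 1 each, centers 1 and 11 -> (1 + 1) / 10
  px2 <- rbind(c(0, 0, 0, 0), c(2, 0, 0, 0), c(10, 0, 0, 0),
               c(12, 0, 0, 0))
  expect_equal(davies_bouldin(px2, c(0, 0, 1, 1)), 0.2)
})

test_that("Davies-Bouldin is scale- and relabel-invariant", {
  set.seed(17)
  px <- matrix(runif(200, 0, 255), 50, 4)
  lab <- rep(c(0, 1), 25)
  base <- davies_bouldin(px, lab)
  expect_equal(davies_bouldin(px * 7.3, lab), base, tolerance = 1e-12)
  expect_equal(davies_bouldin(px, 1 - lab), base, tolerance = 1e-12)
  expect_error(davies_bouldin(px, rep(0, 50)),
               class = "forestseg_validity_error")
})

test_that("ranking sorts ascending and selects the best", {
  set.seed(23)
  mk_item <- function(sd) {
    px <- rbind(matrix(rnorm(200, 0, sd), 50, 4),
                matrix(rnorm(200, 100, sd), 50, 4))
    img <- multiband_image(array(as.raw(pmin(pmax(round(px), 0), 255)),
                                 c(10, 10, 4)))
    list(image = img, mask = matrix(rep(c(1L, 0L), each = 50), 10, 10))
  }
  items <- list(a = mk_item(8), b = mk_item(2), c = mk_item(20))
  r <- rank_and_select(items, top_n = 2)
  expect_equal(r$ranking$image_id, c("b", "a", "c"))
  expect_equal(r$selected_ids, c("b", "a"))
  expect_true(all(diff(r$ranking$db_index) >= 0))
  # boundary: top_n equals the item count
  r_all <- rank_and_select(items, top_n = 3)
  expect_equal(length(r_all$selected_ids), 3L)
  # an item with one empty class is excluded with a reason; if that drops
  # the pool below top_n the selection errors
  items$bad <- list(image = items$a$image, mask = matrix(1L, 10, 10))
  r2 <- rank_and_select(items, top_n = 3)
  expect_equal(r2$excluded$image_id, "bad")
  expect_error(rank_and_select(items["bad"], top_n = 1),
               class = "forestseg_selection_error")
})
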