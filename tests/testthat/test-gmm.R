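test_that("K=1 fit has the closed-form mean and biased covariance", {
  set.seed(4)
  x <- matrix(rnorm(400, mean = 10, sd = 3), 100, 4)
  fit <- fit_gmm(x, 1)
  expect_equal(as.vector(fit$means), colMeans(x))
  n <- nrow(x)
  expected_cov <- crossprod(sweep(x, 2, colMeans(x))) / n
  expect_equal(fit$covariances[[1]], expected_cov + diag(1e-6, 4),
               tolerance = 1e-10)
  expect_equal(fit$weights, 1)
})

test_that("EM recovers two well-separated blobs", {
  set.seed(8)
  x <- rbind(matrix(rnorm(800, 0, 1), 200, 4),
             matrix(rnorm(800, 60, 1), 200, 4))
  fit <- fit_gmm(x, 2, seed = 5)
  mu <- fit$means[order(fit$means[, 1]), ]
  expect_true(all(abs(mu[1, ] - 0) < 1))
  expect_true(all(abs(mu[2, ] - 60) < 1))
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
})

test_that("EM log-likelihood trace is non-decreasing", {
  for (seed in 1:3) {
    out <- generate_scene(default_scene_spec(48, seed = 500 + seed))
    px <- pixel_matrix(out$image)[1:500, ]
    fit <- fit_gmm(px, 3, seed = seed, n_init = 1)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  }
})

test_that("fit_gmm is deterministic under a fixed seed", {
  set.seed(1)
  x <- matrix(runif(800, 0, 255), 200, 4)
  f1 <- fit_gmm(x, 3, seed = 42)
  f2 <- fit_gmm(x, 3, seed = 42)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("fit_gmm enforces its sample-size preconditions", {
  x <- matrix(rnorm(36), 9, 4)
  expect_error(fit_gmm(x, 2), class = "forestseg_input_error")
  expect_error(fit_gmm(x, 0), class = "forestseg_input_error")
})

test_that("diagonal covariance fits have diagonal covariances", {
  set.seed(2)
  x <- matrix(rnorm(800, 50, 5), 200, 4)
  fit <- fit_gmm(x, 2, seed = 3, covariance_type = "diagonal")
  for (s in fit$covariances) {
    expect_equal(s, diag(diag(s), 4))
  }
})

test_that("information criteria follow the AIC/BIC formulas", {
  z <- information_criterion_values(0, 0, 1)
  expect_equal(z$aic, 0)
  expect_equal(z$bic, 0)
  v <- information_criterion_values(-100, 59, 1)
  expect_equal(v$aic, 318)     # 2*59 + 200
  expect_equal(v$bic, 200)     # 59*ln(1) + 200
})

test_that("BIC - AIC equals k (ln N - 2) for fitted models", {
  out <- generate_scene(default_scene_spec(32, seed = 6))
  px <- pixel_matrix(out$image)
  for (K in c(1, 3)) {
    fit <- fit_gmm(px, K, seed = 1)
    ic <- information_criteria(fit, px)
    expect_equal(ic$bic - ic$aic, ic$k * (log(nrow(px)) - 2),
                 tolerance = 1e-9)
  }
})

test_that("mixture log-likelihood matches the brute-force density oracle", {
  out <- generate_scene(default_scene_spec(32, seed = 14))
  px <- pixel_matrix(out$image)
  for (K in c(1, 2, 4)) {
    fit <- fit_gmm(px, K, seed = 2)
    expect_equal(gmm_loglik(fit, px), brute_gmm_loglik(fit, px),
                 tolerance = 1e-6)
  }
  # single-component spot check on a smaller sample
  fit1 <- fit_gmm(px[1:100, ], 1)
  expect_equal(information_criteria(fit1, px[1:100, ])$logL,
               brute_gmm_loglik(fit1, px[1:100, ]), tolerance = 1e-6)
})

test_that("free-parameter counts cover both covariance conventions", {
  expect_identical(n_free_params(1, 4, "full"), 14L)
  expect_identical(n_free_params(4, 4, "full"), 59L)
  expect_identical(n_free_params(10, 4, "diagonal"), 89L)
})

test_that("the regression-form Gaussian log-likelihood is exact", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 3)
  expect_equal(gaussian_regression_loglik(y, yhat, 1),
               -3 / 2 * log(2 * pi))
  y2 <- c(0, 0); yhat2 <- c(1, -1)
  expect_equal(gaussian_regression_loglik(y2, yhat2, 2),
               -log(2 * pi) - log(2) - 0.5)
})

test_that("scan_k produces complete rows with increasing parameter counts", {
  out <- generate_scene(default_scene_spec(48, seed = 10))
  scan <- scan_k(out$image, 2, 5, seed = 1, sample_size = 1000)
  expect_equal(scan$K, 2:5)
  expect_true(all(diff(scan$k) > 0))
  expect_true(all(is.finite(scan$logL)))
  one <- scan_k(out$image, 2, 2, seed = 1, sample_size = 1000)
  expect_equal(nrow(one), 1L)
})

test_that("elbow selection picks the largest slowdown in decrease", {
  scan <- data.frame(K = 2:6, logL = NA, k = 1:5,
                     AIC = c(1000, 400, 390, 385, 383),
                     BIC = c(1000, 400, 390, 385, 383))
  expect_identical(select_k_elbow(scan, "AIC"), 3L)
  # strictly linear decrease: all second differences tie, smallest interior K
  lin <- data.frame(K = 2:6, logL = NA, k = 1:5,
                    AIC = seq(1000, 600, by = -100),
                    BIC = seq(1000, 600, by = -100))
  expect_identical(select_k_elbow(lin, "BIC"), 3L)
  expect_error(select_k_elbow(lin[1:2, ]),
               class = "forestseg_selection_error")
  expect_identical(select_k_elbow(lin, override = 5), 5L)
  expect_error(select_k_elbow(lin, override = 11),
               class = "forestseg_selection_error")
})

test_that("BIC at the true component count beats smaller counts", {
  out <- generate_scene(separable_scene_spec(96, k = 4, seed = 33,
                                             noise_sd = 5))
  scan <- scan_k(out$image, 2, 5, seed = 3, sample_size = 2000)
  bic4 <- scan$BIC[scan$K == 4]
  expect_lt(bic4, scan$BIC[scan$K == 2])
  expect_lt(bic4, scan$BIC[scan$K == 3])
})

test_that("cluster prediction matches the brute-force posterior oracle", {
  out <- generate_scene(default_scene_spec(32, seed = 18))
  px <- pixel_matrix(out$image)
  fit <- fit_gmm(px, 3, seed = 4)
  cmap <- predict_clusters(fit, out$image)
  expect_identical(as.vector(cmap), brute_posteriors(fit, px))
  expect_true(all(cmap >= 0L & cmap < 3L))
})

test_that("prediction at a component mean returns that component", {
  model <- structure(list(
    K = 2L, weights = c(0.5, 0.5),
    means = rbind(c(10, 10, 10, 10), c(200, 200, 200, 200)),
    covariances = list(diag(4, 4), diag(4, 4)),
    covariance_type = "full", seed = 1L, converged = TRUE,
    loglik_trace = 0, ridge_applied = FALSE), class = "gmm_model")
  img <- multiband_image(constant_raster(1, 1, c(200, 200, 200, 200)))
  expect_identical(as.vector(predict_clusters(model, img)), 1L)
  # equidistant pixel with equal weights and covariances: lowest index wins
  mid <- multiband_image(constant_raster(1, 1, c(105, 105, 105, 105)))
  expect_identical(as.vector(predict_clusters(model, mid)), 0L)
})

test_that("EM agrees with mclust on well-separated data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust resolves helpers by search path
  set.seed(12)
  x <- rbind(matrix(rnorm(600, 0, 2), 150, 4),
             matrix(rnorm(600, 40, 2), 150, 4))
  fit <- fit_gmm(x, 2, seed = 9)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  # same maximized log-likelihood (independent EM implementations)
  expect_equal(gmm_loglik(fit, x), as.numeric(mc$loglik), tolerance = 1e-3)
  mu <- fit$means[order(fit$means[, 1]), ]
  mu_mc <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(mu, mu_mc, tolerance = 0.05, ignore_attr = TRUE)
})
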