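# Gaussian mixture fitting and model selection for per-pixel spectra.

#' Fit a Gaussian mixture model to pixel spectra by EM
#'
#' Expectation-maximization with seeded kmeans++-style initialization of
#' the component means, run to convergence (relative log-likelihood change
#' below `tol`) or `max_iter`. Covariances are regularized with a fixed
#' ridge on the diagonal whenever a component degenerates; the event is
#' recorded on the model.
#'
#' @param pixels `N x d` numeric matrix of samples (for imagery, `d = 4`).
#' @param K Number of components (>= 1); `N >= 10 K` is required.
#' @param seed Integer seed making the fit deterministic.
#' @param covariance_type `"full"` (default) or `"diagonal"`.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param ridge Diagonal regularization added to every covariance.
#' @param n_init Number of EM restarts (seeded independently); the run
#'   with the best final log-likelihood is kept. Restarts guard against
#'   the local optima EM is prone to at larger `K`.
#' @return A `gmm_model`: `K`, `weights`, `means` (`K x d`), `covariances`
#'   (list of `d x d`), `covariance_type`, `seed`, `converged`,
#'   `loglik_trace` (one value per EM iteration, non-decreasing), and
#'   `ridge_applied`.
#' @export
fit_gmm <- function(pixels, K, seed = 1L,
                    covariance_type = c("full", "diagonal"),
                    max_iter = 200L, tol = 1e-6, ridge = 1e-6,
                    n_init = 3L) {
  covariance_type <- match.arg(covariance_type)
  stopifnot(n_init >= 1L)
  if (n_init > 1L && K > 1L) {
    fits <- lapply(seq_len(n_init), function(r) {
      fit_gmm(pixels, K,
              seed = if (r == 1L) seed else derive_seed(seed,
                                                        sprintf("restart%d", r)),
              covariance_type = covariance_type, max_iter = max_iter,
              tol = tol, ridge = ridge, n_init = 1L)
    })
    final_ll <- vapply(fits, function(f) f$loglik_trace[length(f$loglik_trace)],
                       numeric(1))
    best <- fits[[which.max(final_ll)]]
    best$seed <- as.integer(seed)
    return(best)
  }
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  n <- nrow(pixels); d <- ncol(pixels)
  if (K < 1L) fs_abort("K must be >= 1", "forestseg_input_error")
  if (n < K) fs_abort("fewer samples than components", "forestseg_input_error")
  if (n < 10L * K) {
    fs_abort(sprintf("fit_gmm needs N >= 10*K samples (N=%d, K=%d)", n, K),
             "forestseg_input_error")
  }

  if (K == 1L) {
    mu <- colMeans(pixels)
    centered <- sweep(pixels, 2L, mu)
    sigma <- crossprod(centered) / n          # biased ML form
    if (covariance_type == "diagonal") sigma <- diag(diag(sigma), d)
    sigma <- sigma + diag(ridge, d)
    ll <- sum(dmvnorm_log(pixels, mu, sigma))
    return(structure(list(K = 1L, weights = 1, means = matrix(mu, 1L, d),
                          covariances = list(sigma),
                          covariance_type = covariance_type,
                          seed = as.integer(seed), converged = TRUE,
                          loglik_trace = ll, ridge_applied = FALSE),
                     class = "gmm_model"))
  }

  with_seed(seed, {
    means <- kmeanspp_init(pixels, K)
    # hard-assignment M-step to get starting parameters
    d2 <- pairwise_sqdist(pixels, means)
    assign0 <- max.col(-d2, ties.method = "first")
    weights <- numeric(K)
    covs <- vector("list", K)
    global_cov <- stats::cov(pixels) + diag(ridge, d)
    for (k in seq_len(K)) {
      idx <- which(assign0 == k)
      weights[k] <- max(length(idx), 1) / n
      if (length(idx) > d) {
        means[k, ] <- colMeans(pixels[idx, , drop = FALSE])
        ctr <- sweep(pixels[idx, , drop = FALSE], 2L, means[k, ])
        covs[[k]] <- crossprod(ctr) / length(idx) + diag(ridge, d)
      } else {
        covs[[k]] <- global_cov
      }
    }
    weights <- weights / sum(weights)
    if (covariance_type == "diagonal") {
      covs <- lapply(covs, function(s) diag(diag(s), d))
    }

    trace <- numeric(0)
    converged <- FALSE
    ridge_applied <- FALSE
    prev_ll <- -Inf
    for (iter in seq_len(max_iter)) {
      # E-step in log space
      logdens <- component_logdens(pixels, weights, means, covs)
      m <- apply(logdens, 1L, max)
      lse <- m + log(rowSums(exp(logdens - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(logdens - lse)

      if (is.finite(prev_ll) &&
          abs(ll - prev_ll) <= tol * abs(prev_ll)) {
        converged <- TRUE
        break
      }
      prev_ll <- ll

      # M-step
      nk <- colSums(resp)
      nk <- pmax(nk, 1e-10)
      weights <- nk / n
      means <- crossprod(resp, pixels) / nk
      for (k in seq_len(K)) {
        ctr <- sweep(pixels, 2L, means[k, ])
        s <- crossprod(ctr * resp[, k], ctr) / nk[k]
        if (covariance_type == "diagonal") s <- diag(diag(s), d)
        s <- s + diag(ridge, d)
        if (inherits(try(chol(s), silent = TRUE), "try-error")) {
          s <- s + diag(1e-3, d)
          ridge_applied <- TRUE
        }
        covs[[k]] <- s
      }
    }
    structure(list(K = as.integer(K), weights = as.numeric(weights),
                   means = means, covariances = covs,
                   covariance_type = covariance_type,
                   seed = as.integer(seed), converged = converged,
                   loglik_trace = trace, ridge_applied = ridge_applied),
              class = "gmm_model")
  })
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K=%d, %s covariances, %s (%d EM iterations)\n",
              x$K, x$covariance_type,
              if (x$converged) "converged" else "not converged",
              length(x$loglik_trace)))
  invisible(x)
}

# kmeans++ seeding: first center uniform, then D^2-weighted.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  min_d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (k in 2:K) {
    p <- min_d2 / sum(min_d2)
    if (!all(is.finite(p)) || sum(min_d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = p)
    }
    centers[k, ] <- x[idx, ]
    min_d2 <- pmin(min_d2, rowSums(sweep(x, 2L, centers[k, ])^2))
  }
  centers
}

pairwise_sqdist <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

# Log density of N(mu, sigma) at the rows of x, via Cholesky.
dmvnorm_log <- function(x, mu, sigma) {
  d <- ncol(x)
  L <- chol(sigma)
  ctr <- sweep(x, 2L, mu)
  # solve R^T u = ctr^T (R upper Cholesky) => quadratic form = colSums(u^2)
  u <- backsolve(L, t(ctr), transpose = TRUE)
  q <- colSums(u^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + q)
}

# N x K matrix of log(w_k) + log N(x | mu_k, sigma_k).
component_logdens <- function(x, weights, means, covs) {
  K <- length(weights)
  out <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    out[, k] <- log(weights[k]) + dmvnorm_log(x, means[k, ], covs[[k]])
  }
  out
}

#' Mixture log-likelihood of pixels under a fitted model
#'
#' @param model A `gmm_model`.
#' @param pixels `N x d` matrix.
#' @return Total log-likelihood (sum over pixels of the log of the
#'   weighted component densities).
#' @export
gmm_loglik <- function(model, pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  logdens <- component_logdens(pixels, model$weights, model$means,
                               model$covariances)
  m <- apply(logdens, 1L, max)
  sum(m + log(rowSums(exp(logdens - m))))
}

#' Number of free parameters of a K-component Gaussian mixture
#'
#' Full covariances: `(K-1) + K d + K d(d+1)/2`; diagonal: `(K-1) + 2 K d`.
#'
#' @param K Component count.
#' @param d Data dimension (default 4 bands).
#' @param covariance_type `"full"` or `"diagonal"`.
#' @return Integer parameter count.
#' @export
n_free_params <- function(K, d = 4L, covariance_type = c("full", "diagonal")) {
  covariance_type <- match.arg(covariance_type)
  stopifnot(K >= 1L, d >= 1L)
  cov_terms <- if (covariance_type == "full") d * (d + 1) / 2 else d
  as.integer((K - 1) + K * d + K * cov_terms)
}

#' Information-criterion values from summary statistics
#'
#' `AIC = 2k - 2 logL` and `BIC = k ln(N) - 2 logL`, where `k` is the
#' number of free parameters and `N` the number of samples.
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of samples.
#' @return Named list `aic`, `bic`.
#' @export
information_criterion_values <- function(logL, k, n) {
  list(aic = 2 * k - 2 * logL, bic = k * log(n) - 2 * logL)
}

#' Log-likelihood and information criteria of a model on data
#'
#' @param model A fitted `gmm_model`.
#' @param pixels `N x d` matrix the model is scored on.
#' @return Named list `logL`, `k`, `aic`, `bic`.
#' @export
information_criteria <- function(model, pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) {
    fs_abort("information_criteria needs at least one pixel",
             "forestseg_input_error")
  }
  logL <- gmm_loglik(model, pixels)
  k <- n_free_params(model$K, ncol(pixels), model$covariance_type)
  ic <- information_criterion_values(logL, k, nrow(pixels))
  list(logL = logL, k = k, aic = ic$aic, bic = ic$bic)
}

#' Gaussian regression-style log-likelihood
#'
#' The textbook Gaussian likelihood of residuals between observed targets
#' and predictions under a known noise variance:
#' `-N/2 log(2 pi) - N/2 ln(sigma^2) - sum((y - yhat)^2) / (2 sigma^2)`.
#' Provided as a standalone utility; the clustering model-selection path
#' uses the mixture log-likelihood ([gmm_loglik()]) instead, since an
#' unsupervised clustering has no per-pixel targets or known variance.
#'
#' @param y Observed targets.
#' @param yhat Predicted values (same length).
#' @param sigma2 Known noise variance (> 0).
#' @return Log-likelihood value.
#' @export
gaussian_regression_loglik <- function(y, yhat, sigma2) {
  stopifnot(length(y) == length(yhat), sigma2 > 0)
  n <- length(y)
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) -
    sum((y - yhat)^2) / (2 * sigma2)
}

#' Scan candidate component counts
#'
#' Fits one mixture per `K` in `[k_min, k_max]` (every fit drawn from the
#' same seeded subsample and the same per-K derived seed policy) and
#' tabulates log-likelihood, parameter count, AIC, and BIC.
#'
#' @param image A [multiband_image()] or an `N x d` pixel matrix.
#' @param k_min,k_max Scan range (`k_min >= 2`).
#' @param seed Master seed for subsampling and fits.
#' @param sample_size Maximum number of pixels used for fitting; larger
#'   inputs are subsampled (seeded). Criteria are evaluated on the fitting
#'   sample so all rows share one `N`.
#' @param covariance_type,max_iter,tol Passed to [fit_gmm()].
#' @return A `criterion_scan`: data frame with columns `K`, `logL`, `k`,
#'   `AIC`, `BIC`, plus attributes `models` (list of fits) and `n`.
#' @export
scan_k <- function(image, k_min = 2L, k_max = 10L, seed = 1L,
                   sample_size = 20000L,
                   covariance_type = c("full", "diagonal"),
                   max_iter = 200L, tol = 1e-6) {
  covariance_type <- match.arg(covariance_type)
  if (k_min < 2L) fs_abort("k_min must be >= 2", "forestseg_input_error")
  if (k_max < k_min) fs_abort("k_max must be >= k_min",
                              "forestseg_input_error")
  pixels <- if (inherits(image, "multiband_image")) {
    pixel_matrix(image)
  } else {
    as.matrix(image)
  }
  if (nrow(pixels) > sample_size) {
    idx <- with_seed(derive_seed(seed, "scan_subsample"),
                     sample.int(nrow(pixels), sample_size))
    pixels <- pixels[idx, , drop = FALSE]
  }
  ks <- k_min:k_max
  models <- vector("list", length(ks))
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    fit <- tryCatch(
      fit_gmm(pixels, K, seed = derive_seed(seed, "gmm_fit"),
              covariance_type = covariance_type,
              max_iter = max_iter, tol = tol),
      error = function(e) {
        fs_abort(sprintf("GMM fit failed at K=%d: %s", K,
                         conditionMessage(e)), "forestseg_fit_error")
      })
    ic <- information_criteria(fit, pixels)
    models[[i]] <- fit
    rows[[i]] <- data.frame(K = K, logL = ic$logL, k = ic$k,
                            AIC = ic$aic, BIC = ic$bic)
  }
  scan <- do.call(rbind, rows)
  attr(scan, "models") <- models
  attr(scan, "n") <- nrow(pixels)
  class(scan) <- c("criterion_scan", "data.frame")
  scan
}

#' Pick the number of clusters at the criterion elbow
#'
#' Returns the `K` where the criterion's decrease slows down the most: the
#' interior point maximizing the second difference
#' `C(K-1) - 2 C(K) + C(K+1)`. Ties break toward smaller `K`. A manual
#' override short-circuits the rule.
#'
#' @param scan A `criterion_scan` from [scan_k()].
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param override Optional manual `K` (must be in the scan).
#' @return Selected integer `K`.
#' @export
select_k_elbow <- function(scan, criterion = c("BIC", "AIC"),
                           override = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(override)) {
    if (!override %in% scan$K) {
      fs_abort("override K is not in the scan", "forestseg_selection_error")
    }
    return(as.integer(override))
  }
  if (nrow(scan) < 3L) {
    fs_abort("elbow selection needs a scan of at least 3 component counts",
             "forestseg_selection_error")
  }
  v <- scan[[criterion]]
  n <- length(v)
  d2 <- v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]   # at interior K
  as.integer(scan$K[1L + which.max(d2)])           # which.max -> smallest tie
}

#' Assign every pixel to its maximum-posterior component
#'
#' @param model A fitted `gmm_model` of dimension 4.
#' @param image A [multiband_image()].
#' @return A `cluster_map`: `H x W` integer matrix of 0-based component
#'   labels (ties go to the lowest-index component), with attribute `K`.
#' @export
predict_clusters <- function(model, image) {
  stopifnot(inherits(image, "multiband_image"))
  if (ncol(model$means) != 4L) {
    fs_abort("model dimension must be 4 to score RGBN imagery",
             "forestseg_input_error")
  }
  px <- pixel_matrix(image)
  logdens <- component_logdens(px, model$weights, model$means,
                               model$covariances)
  lab <- max.col(logdens, ties.method = "first") - 1L
  d <- dim(image$pixels)
  structure(matrix(as.integer(lab), d[1], d[2]), K = model$K,
            class = c("cluster_map", "matrix"))
}
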