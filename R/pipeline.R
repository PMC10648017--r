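# End-to-end orchestration: label -> rank -> tile -> split -> train ->
# evaluate, with one master seed driving every stochastic stage.

#' Configuration for an end-to-end run
#'
#' @param n_images Number of input scenes (synthetic source) or `NULL`
#'   when `input_dir` is given.
#' @param scene_size Synthetic scene side in pixels.
#' @param input_dir Optional directory of `.npy` / `.tif` 4-band rasters
#'   used instead of synthetic scenes.
#' @param scene_noise_sd Noise level passed to the synthetic generator.
#' @param k_min,k_max Component scan range.
#' @param criterion `"BIC"` or `"AIC"` for elbow selection.
#' @param merge `"auto"` or an integer vector of 0-based components.
#' @param adjacency_threshold Auto-merge adjacency threshold.
#' @param median_size,closing_size Mask filter kernel sides (odd).
#' @param top_n Images selected by Davies-Bouldin ranking.
#' @param tile Tile side (power of two).
#' @param n_test,val_fraction Split sizes.
#' @param scenarios Integer vector of U-Net scenarios to train.
#' @param train A [train_config()].
#' @param scan_sample_size Pixels subsampled for the criterion scan.
#' @param output_dir Optional directory where every intermediate is
#'   persisted (scan and ranking CSVs, masks, dataset, histories).
#' @param seed Master seed; per-stage seeds derive from it.
#' @return A `run_config`.
#' @export
run_config <- function(n_images = 10L, scene_size = 128L, input_dir = NULL,
                       scene_noise_sd = 5, k_min = 2L, k_max = 10L,
                       criterion = "BIC", merge = "auto",
                       adjacency_threshold = 0.10,
                       median_size = 9L, closing_size = 9L, top_n = 16L,
                       tile = 128L, n_test = 4400L, val_fraction = 0.10,
                       scenarios = 6L, train = train_config(),
                       scan_sample_size = 20000L, output_dir = NULL,
                       seed = 1L) {
  structure(list(n_images = n_images, scene_size = scene_size,
                 input_dir = input_dir, scene_noise_sd = scene_noise_sd,
                 k_min = k_min, k_max = k_max, criterion = criterion,
                 merge = merge, adjacency_threshold = adjacency_threshold,
                 median_size = median_size, closing_size = closing_size,
                 top_n = top_n, tile = tile, n_test = n_test,
                 val_fraction = val_fraction, scenarios = scenarios,
                 train = train, scan_sample_size = scan_sample_size,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "output_dir")], tmp)
  unname(tools::md5sum(tmp))
}

# Load images from a directory (npy/tif) or synthesize them.
acquire_images <- function(config) {
  if (!is.null(config$input_dir)) {
    paths <- sort(list.files(config$input_dir,
                             pattern = "\\.(npy|tif|tiff)$",
                             full.names = TRUE))
    if (!length(paths)) {
      fs_abort(sprintf("no rasters found in '%s'", config$input_dir),
               "forestseg_io_error")
    }
    images <- lapply(paths, function(p) multiband_image(load_array(p)))
    list(images = images, truths = NULL,
         ids = tools::file_path_sans_ext(basename(paths)))
  } else {
    n <- config$n_images
    scenes <- lapply(seq_len(n), function(i) {
      generate_scene(default_scene_spec(
        config$scene_size, noise_sd = config$scene_noise_sd,
        seed = derive_seed(config$seed, sprintf("scene%03d", i))))
    })
    list(images = lapply(scenes, `[[`, "image"),
         truths = lapply(scenes, `[[`, "truth"),
         ids = sprintf("image_%03d", seq_len(n)))
  }
}

#' Label one image end to end
#'
#' The per-image labeling core: scan component counts, select the elbow,
#' predict clusters, merge into forest/no-forest, and filter the mask.
#'
#' @param image A [multiband_image()].
#' @param k_min,k_max,criterion,merge,adjacency_threshold,median_size,closing_size,scan_sample_size
#'   As in [run_config()].
#' @param seed Master seed for the scan.
#' @return List with `mask` (filtered `binary_mask`), `raw_mask`,
#'   `scan`, `selected_k`, `model`, `rule`, `cmap`.
#' @export
label_image <- function(image, k_min = 2L, k_max = 10L, criterion = "BIC",
                        merge = "auto", adjacency_threshold = 0.10,
                        median_size = 9L, closing_size = 9L,
                        scan_sample_size = 20000L, seed = 1L) {
  scan <- scan_k(image, k_min = k_min, k_max = k_max, seed = seed,
                 sample_size = scan_sample_size)
  selected_k <- select_k_elbow(scan, criterion = criterion)
  model <- attr(scan, "models")[[match(selected_k, scan$K)]]
  cmap <- predict_clusters(model, image)
  rule <- if (identical(merge, "auto")) {
    auto_merge_rule(model, cmap, adjacency_threshold = adjacency_threshold)
  } else {
    manual_merge_rule(merge)
  }
  raw_mask <- apply_merge(cmap, rule)
  mask <- postprocess_mask(raw_mask, median_size = median_size,
                           closing_size = closing_size)
  list(mask = mask, raw_mask = raw_mask, scan = scan,
       selected_k = selected_k, model = model, rule = rule, cmap = cmap)
}

# Stages up to the dataset split, shared by run_pipeline / lr_sweep /
# scenario_report. The mixture is fitted once on the training image and
# its centers and merge rule are reused to predict labels for the whole
# image set.
prepare_labeled_dataset <- function(config, train_image = 1L) {
  src <- acquire_images(config)
  images <- src$images
  n <- length(images)
  if (config$top_n > n) {
    fs_abort(sprintf("top_n=%d exceeds the %d available images",
                     config$top_n, n), "forestseg_selection_error")
  }
  lab <- label_image(images[[train_image]], k_min = config$k_min,
                     k_max = config$k_max, criterion = config$criterion,
                     merge = config$merge,
                     adjacency_threshold = config$adjacency_threshold,
                     median_size = config$median_size,
                     closing_size = config$closing_size,
                     scan_sample_size = config$scan_sample_size,
                     seed = derive_seed(config$seed, "gmm"))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cmap <- if (i == train_image) lab$cmap
            else predict_clusters(lab$model, images[[i]])
    raw <- apply_merge(cmap, lab$rule)
    masks[[i]] <- postprocess_mask(raw, median_size = config$median_size,
                                   closing_size = config$closing_size)
  }
  items <- Map(function(img, m) list(image = img, mask = m), images, masks)
  names(items) <- src$ids
  ranking <- rank_and_select(items, top_n = config$top_n)
  sel <- match(ranking$selected_ids, src$ids)
  samples <- build_dataset(images[sel], masks[sel], tile = config$tile,
                           ids = src$ids[sel])
  n_test <- min(config$n_test, max(length(samples) - 1L, 0L))
  split <- split_dataset(samples, n_test = n_test,
                         val_fraction = config$val_fraction,
                         seed = derive_seed(config$seed, "split"))
  list(src = src, labeling = lab, masks = masks, ranking = ranking,
       samples = samples, split = split)
}

persist_prepared <- function(prep, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scan_csv(prep$labeling$scan, file.path(dir, "criterion_scan.csv"))
  write_ranking_csv(prep$ranking, file.path(dir, "db_ranking.csv"))
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (i in seq_along(prep$masks)) {
    write_npy(prep$masks[[i]],
              file.path(mask_dir, paste0(prep$src$ids[i], ".npy")))
  }
  write_dataset(prep$split, file.path(dir, "dataset"))
  invisible(NULL)
}

#' Run the full workflow
#'
#' Executes scan, elbow selection, cluster prediction, merging, filtering,
#' validity ranking, tiling, splitting, training, and evaluation in order,
#' persisting every intermediate when `output_dir` is set. Identical
#' config and seed reproduce the report exactly.
#'
#' @param config A [run_config()].
#' @return A `run_report`: criterion scan, selected K, merge rule, DB
#'   ranking, dataset counts, per-scenario ledger totals and evaluation
#'   results, ground-truth pixel agreement (synthetic sources only), and
#'   provenance (config hash, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  with_stage <- function(stage, expr) {
    tryCatch(expr, forestseg_error = function(e) {
      stop(structure(class = c(class(e), "forestseg_stage_error"),
                     list(message = sprintf("[stage %s] %s", stage,
                                            conditionMessage(e)),
                          call = conditionCall(e), stage = stage)))
    })
  }
  prep <- with_stage("labeling", prepare_labeled_dataset(config))
  persist_prepared(prep, config)

  agreement <- NULL
  if (!is.null(prep$src$truths)) {
    agreement <- vapply(seq_along(prep$masks), function(i) {
      mean(prep$masks[[i]] == prep$src$truths[[i]]$mask)
    }, numeric(1))
  }

  results <- list()
  for (s in config$scenarios) {
    spec <- unet_spec(scenario = s)
    ledger <- count_parameters(spec)
    model <- build_model(spec, seed = derive_seed(config$seed,
                                                  sprintf("init%d", s)))
    tr <- with_stage(sprintf("train_scenario%d", s),
                     train_model(model, prep$split, config$train))
    ev <- if (length(prep$split$test)) {
      with_stage(sprintf("evaluate_scenario%d", s),
                 evaluate_model(tr$model, prep$split$test))
    } else {
      NULL
    }
    if (!is.null(config$output_dir)) {
      utils::write.csv(tr$history,
                       file.path(config$output_dir,
                                 sprintf("history_scenario%d.csv", s)),
                       row.names = FALSE)
      write_ledger_csv(ledger,
                       file.path(config$output_dir,
                                 sprintf("ledger_scenario%d.csv", s)))
    }
    results[[as.character(s)]] <- list(
      scenario = s, total_kernels = count_kernels(spec),
      total_parameters = attr(ledger, "total_parameters"),
      history = tr$history, eval = ev, model = tr$model)
  }

  structure(list(
    scan = prep$labeling$scan, selected_k = prep$labeling$selected_k,
    merge_rule = prep$labeling$rule, ranking = prep$ranking,
    counts = list(images = length(prep$src$images),
                  tiles = length(prep$samples),
                  train = length(prep$split$train),
                  validation = length(prep$split$validation),
                  test = length(prep$split$test)),
    truth_agreement = agreement, scenarios = results,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("forestseg")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> K=%d, %d/%d images selected, %d tiles (%d/%d/%d)\n",
              x$selected_k, sum(x$ranking$ranking$selected),
              nrow(x$ranking$ranking) + nrow(x$ranking$excluded),
              x$counts$tiles, x$counts$train, x$counts$validation,
              x$counts$test))
  for (r in x$scenarios) {
    cat(sprintf("  scenario %d: %s params%s\n", r$scenario,
                format(r$total_parameters, big.mark = ","),
                if (!is.null(r$eval)) sprintf(", test acc %.4f",
                                              r$eval$pixel_accuracy)
                else ""))
  }
  invisible(x)
}

#' Learning-rate sweep
#'
#' Trains one model per candidate rate on the same data, with the same
#' seeds (so weight initialization and batch order are shared), and
#' tabulates final training/validation metrics. A diverging rate is
#' recorded and the sweep continues.
#'
#' @param config A [run_config()]; its first listed scenario is swept.
#' @param rates Learning rates (default the common negative powers of ten
#'   `1e-2, 1e-3, 1e-4, 1e-5`).
#' @return List with `histories` (per rate) and `table` (one row per
#'   rate: final train/validation loss and accuracy, divergence flag).
#' @export
lr_sweep <- function(config, rates = c(1e-2, 1e-3, 1e-4, 1e-5)) {
  stopifnot(inherits(config, "run_config"), length(rates) >= 1L)
  prep <- prepare_labeled_dataset(config)
  s <- config$scenarios[1]
  spec <- unet_spec(scenario = s)
  histories <- list()
  rows <- list()
  for (r in rates) {
    cfg <- config$train
    cfg$alpha <- r
    model <- build_model(spec, seed = derive_seed(config$seed,
                                                  sprintf("init%d", s)))
    res <- tryCatch(train_model(model, prep$split, cfg),
                    forestseg_divergence_error = function(e) e)
    if (inherits(res, "condition")) {
      histories[[sprintf("%g", r)]] <- NULL
      rows[[length(rows) + 1L]] <- data.frame(
        rate = r, train_loss = NA, train_acc = NA, val_loss = NA,
        val_acc = NA, diverged = TRUE)
    } else {
      h <- res$history
      last <- h[nrow(h), ]
      histories[[sprintf("%g", r)]] <- h
      rows[[length(rows) + 1L]] <- data.frame(
        rate = r, train_loss = last$train_loss, train_acc = last$train_acc,
        val_loss = last$val_loss, val_acc = last$val_acc, diverged = FALSE)
    }
  }
  list(histories = histories, table = do.call(rbind, rows))
}

#' Scenario comparison table
#'
#' One row per scenario: analytic kernel and parameter totals (from the
#' ledger, never measured) plus, when `train_models` is `TRUE`, test
#' accuracy and F1 from models trained on the prepared dataset.
#'
#' @param config A [run_config()].
#' @param scenarios Scenarios to tabulate (default 1:6).
#' @param train_models Whether to train and evaluate each scenario.
#' @return Data frame `scenario`, `total_kernels`, `trainable_parameters`,
#'   `test_accuracy`, `f1_score`.
#' @export
scenario_report <- function(config, scenarios = 1:6, train_models = FALSE) {
  if (!length(scenarios)) {
    return(data.frame(scenario = integer(0), total_kernels = integer(0),
                      trainable_parameters = numeric(0),
                      test_accuracy = numeric(0), f1_score = numeric(0)))
  }
  prep <- if (train_models) prepare_labeled_dataset(config) else NULL
  rows <- lapply(scenarios, function(s) {
    spec <- unet_spec(scenario = s)
    acc <- f1 <- NA_real_
    if (train_models) {
      model <- build_model(spec, seed = derive_seed(config$seed,
                                                    sprintf("init%d", s)))
      tr <- train_model(model, prep$split, config$train)
      ev <- evaluate_model(tr$model, prep$split$test)
      acc <- ev$pixel_accuracy; f1 <- ev$f1_score
    }
    data.frame(scenario = s, total_kernels = count_kernels(spec),
               trainable_parameters = total_parameters(spec),
               test_accuracy = acc, f1_score = f1)
  })
  do.call(rbind, rows)
}
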