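#' Assemble model-ready inputs for one cross-validation fold
#'
#' Runs the fold-dependent tail of the preprocessing pipeline: fits the
#' per-channel scaler on the fold's training tensors only, applies it to
#' both sides, resets padding columns to exactly 0 (the neutral value), and
#' stacks either encoded 95 x 95 x 3 images (image models) or 750 x 36
#' frame-major sequences (`cnn_lstm`).
#'
#' @param trials Trials tibble that has been through [filter_trials()] and
#'   [pad_trials()].
#' @param fold One row of the [make_folds()] tibble (or a list with
#'   `train`/`test` integer index vectors).
#' @param representation `"image"` or `"sequence"`.
#' @param scaler_mode Passed to [fit_scaler()].
#' @return List with `x_train`, `y_train`, `x_test`, `y_test`, `scaler`,
#'   and the index vectors.
#' @export
build_fold_data <- function(trials, fold, representation = c("image", "sequence"),
                            scaler_mode = "zscore") {
  representation <- match.arg(representation)
  stopifnot("tensor" %in% names(trials))
  train_idx <- if (is.data.frame(fold)) fold$train[[1]] else fold$train
  test_idx <- if (is.data.frame(fold)) fold$test[[1]] else fold$test
  scaler <- fit_scaler(trials$tensor[train_idx], mode = scaler_mode)
  prep <- function(idx) {
    tensors <- apply_scaler(trials$tensor[idx], scaler,
                            pad_start = trials$pad_start[idx])
    if (representation == "image") {
      x <- array(0, dim = c(95L, 95L, 3L, length(idx)))
      for (i in seq_along(tensors)) x[, , , i] <- encode_image(tensors[[i]])
    } else {
      frames <- dim(tensors[[1]])[2]
      x <- array(0, dim = c(frames, 36L, length(idx)))
      for (i in seq_along(tensors)) {
        # tensor (12, frames, 3) -> frames x 36 features, feature order =
        # stream-major then axis, matching channel_layout()
        x[, , i] <- t(matrix(aperm(tensors[[i]], c(3, 1, 2)), 36L, frames))
      }
    }
    x
  }
  list(x_train = prep(train_idx), y_train = trials$risk[train_idx],
       x_test = prep(test_idx), y_test = trials$risk[test_idx],
       scaler = scaler, train = train_idx, test = test_idx)
}

#' Train on one fold and evaluate on its test side
#'
#' @param fold_data Output of [build_fold_data()].
#' @param spec A [model_spec()].
#' @param config A [training_config()].
#' @return List with the trained `model`, test `confusion` matrix,
#'   `metrics` report and `predicted` labels.
#' @export
evaluate_fold <- function(fold_data, spec, config = training_config()) {
  model <- build_model(spec, seed = config$seed)
  model <- train_model(model, fold_data$x_train, fold_data$y_train, config)
  pred <- predict(model, fold_data$x_test, type = "class")
  C <- confusion_matrix(fold_data$y_test, pred)
  list(model = model, confusion = C, metrics = metrics_report(C),
       predicted = pred)
}

#' Cross-validated hyperparameter sweep
#'
#' Trains one model per grid setting on every fold and reports the mean
#' cross-validated R_K and accuracy. Selection by highest R_K is the
#' default recommendation, but both metrics are returned because they can
#' rank settings differently; pass a `select` function to override (e.g.
#' to prefer a more stable learning rate).
#'
#' @param fold_data_list List of [build_fold_data()] outputs (fixed across
#'   settings).
#' @param grid Data frame with columns among `lambda`, `alpha`, `dropout`.
#' @param name Architecture name for [model_spec()].
#' @param config Base [training_config()]; `alpha` overrides its learning
#'   rate per setting.
#' @param ... Extra arguments to [model_spec()].
#' @return Tibble: one row per setting with `lambda`, `alpha`, `dropout`,
#'   `mean_r_k`, `mean_accuracy`.
#' @export
hyperparameter_sweep <- function(fold_data_list, grid,
                                 name = "proposed_avgpool",
                                 config = training_config(), ...) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    abort("empty hyperparameter grid", class = "liftrisk_config_error")
  }
  defaults <- list(lambda = 1e-5, alpha = config$learning_rate, dropout = 0.25)
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- model_spec(name, dropout = grid$dropout[i],
                       l2_lambda = grid$lambda[i], ...)
    cfg <- config
    cfg$learning_rate <- grid$alpha[i]
    res <- lapply(fold_data_list, evaluate_fold, spec = spec, config = cfg)
    tibble::tibble(lambda = grid$lambda[i], alpha = grid$alpha[i],
                   dropout = grid$dropout[i],
                   mean_r_k = mean(vapply(res, function(r) r$metrics$r_k,
                                          numeric(1))),
                   mean_accuracy = mean(vapply(res,
                                               function(r) r$metrics$accuracy,
                                               numeric(1))))
  })
  dplyr::bind_rows(rows)
}

#' Pool fold confusion matrices to a single test-set scale
#'
#' Averages the per-fold count matrices and rounds back to integers with a
#' largest-remainder correction so the pooled total equals one test-set
#' size. Per-fold matrices should be retained alongside, since rounding
#' loses information.
#'
#' @param confusions List of equal-sized confusion matrices.
#' @return Integer `conf_mat` of the same shape.
#' @export
pool_confusions <- function(confusions) {
  stopifnot(length(confusions) >= 1)
  avg <- Reduce(`+`, lapply(confusions, unclass)) / length(confusions)
  pooled <- matrix(largest_remainder_round(as.vector(avg)),
                   nrow(avg), ncol(avg), dimnames = dimnames(avg))
  structure(pooled, class = c("conf_mat", "matrix"))
}

#' Experiment configuration
#'
#' One nested configuration drives the full pipeline: simulate ->
#' band-pass filter -> pad -> per-zone stratified folds -> per-fold scale +
#' encode -> train -> evaluate -> (optionally) saliency. Every stage seed
#' is derived deterministically from the global `seed`. Configurations
#' round-trip through YAML via [read_experiment_config()] /
#' [write_experiment_config()].
#'
#' @param seed Global integer seed.
#' @param sim Named list of [sim_config()] overrides.
#' @param filter Named list of [filter_spec()] overrides.
#' @param scaler_mode `"zscore"` or `"minmax"`.
#' @param folds Named list: `n_folds`, `test_fraction`, `by_subject`.
#' @param model Named list of [model_spec()] arguments (needs `name`).
#' @param train Named list of [training_config()] overrides.
#' @param saliency Compute class-average saliency maps on each fold's test
#'   side? (`FALSE` by default; adds one backward pass per test trial.)
#' @param out_dir Optional directory for artifacts (config snapshot, fold
#'   assignments, per-fold metrics, pooled confusion matrix, histories,
#'   log).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L, sim = list(), filter = list(),
                              scaler_mode = "zscore",
                              folds = list(n_folds = 4L, test_fraction = 0.25,
                                           by_subject = FALSE),
                              model = list(name = "proposed_avgpool"),
                              train = list(), saliency = FALSE,
                              out_dir = NULL) {
  structure(list(seed = as.integer(seed), sim = sim, filter = filter,
                 scaler_mode = scaler_mode,
                 folds = modifyList(list(n_folds = 4L, test_fraction = 0.25,
                                         by_subject = FALSE), folds),
                 model = modifyList(list(name = "proposed_avgpool"), model),
                 train = train, saliency = isTRUE(saliency),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

derive_seed <- function(seed, offset) (abs(seed) %% 100000L) * 7919L + offset

#' Run the full lifting-risk experiment
#'
#' Executes every stage on synthetic trials and returns fold-wise and
#' pooled results. The pooled confusion matrix follows the
#' average-then-rescale convention (one test-set size); per-fold matrices
#' are kept because both fold-mean metrics and pooled-matrix metrics are
#' of interest and can differ slightly.
#'
#' @param config An [experiment_config()].
#' @return A `lift_experiment` object: `config`, `trials` (metadata
#'   without signals), `folds`, `fold_results` (confusion, metrics,
#'   history, predictions per fold), `pooled_confusion`, `pooled_metrics`,
#'   `fold_mean` (mean accuracy / R_K across folds), optional `saliency`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "liftrisk_stage_error", parent = e)
    })
  }
  scfg <- do.call(sim_config, modifyList(config$sim,
                                         list(seed = derive_seed(config$seed, 101L))))
  fspec <- do.call(filter_spec, config$filter)
  say("simulate: %d subjects x 12 zones x %d trials", scfg$n_subjects,
      scfg$trials_per_zone_per_subject)
  trials <- stage("simulate", simulate_lifts(scfg))
  say("preprocess: Butterworth order %d band %g-%g Hz (zero-phase), pad to 750, scaler=%s, pad reset to 0, row-major time-major wrap",
      fspec$order, fspec$low_cut, fspec$high_cut, config$scaler_mode)
  trials <- stage("filter", filter_trials(trials, fspec))
  trials <- stage("pad", pad_trials(trials))
  folds <- stage("split", make_folds(trials, n_folds = config$folds$n_folds,
                                     test_fraction = config$folds$test_fraction,
                                     seed = derive_seed(config$seed, 202L),
                                     by_subject = isTRUE(config$folds$by_subject)))
  spec <- do.call(model_spec, config$model)
  representation <- if (spec$name == "cnn_lstm") "sequence" else "image"
  fold_results <- vector("list", nrow(folds))
  sal_maps <- list()
  for (f in seq_len(nrow(folds))) {
    say("fold %d/%d: train %s on %d trials, test on %d", f, nrow(folds),
        spec$name, length(folds$train[[f]]), length(folds$test[[f]]))
    fd <- stage("prepare", build_fold_data(trials, folds[f, ],
                                           representation = representation,
                                           scaler_mode = config$scaler_mode))
    cfg <- do.call(training_config,
                   modifyList(config$train,
                              list(seed = derive_seed(config$seed, 300L + f))))
    res <- stage("train", evaluate_fold(fd, spec, cfg))
    say("fold %d: accuracy %.3f, R_K %.3f (best epoch %d)", f,
        res$metrics$accuracy, res$metrics$r_k, res$model$best_epoch)
    if (config$saliency) {
      sal_maps[[f]] <- lapply(risk_levels(), function(cl) {
        if (!any(fd$y_test == cl)) return(NULL)
        saliency_class_average(res$model, fd$x_test, fd$y_test, cl)
      })
    }
    fold_results[[f]] <- list(fold = f, confusion = res$confusion,
                              metrics = res$metrics,
                              history = res$model$history,
                              predicted = res$predicted,
                              test = fd$test)
    res$model <- NULL
  }
  pooled <- pool_confusions(lapply(fold_results, `[[`, "confusion"))
  pooled_metrics <- metrics_report(pooled)
  fold_mean <- tibble::tibble(
    accuracy = mean(vapply(fold_results, function(r) r$metrics$accuracy,
                           numeric(1))),
    r_k = mean(vapply(fold_results, function(r) r$metrics$r_k, numeric(1)))
  )
  say("pooled (scaled to one test set of %d): accuracy %.3f, R_K %.3f",
      sum(pooled), pooled_metrics$accuracy, pooled_metrics$r_k)
  out <- structure(list(
    config = config,
    trials = dplyr::select(trials, -dplyr::any_of(c("frames", "tensor"))),
    folds = folds,
    fold_results = fold_results,
    pooled_confusion = pooled,
    pooled_metrics = pooled_metrics,
    fold_mean = fold_mean,
    saliency = if (config$saliency) sal_maps else NULL,
    log = log_lines
  ), class = "lift_experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_config(exp$config, file.path(dir, "config.yaml"))
  assignments <- dplyr::bind_rows(lapply(seq_len(nrow(exp$folds)), function(f) {
    tibble::tibble(fold = f,
                   trial_id = c(exp$folds$train[[f]], exp$folds$test[[f]]),
                   role = rep(c("train", "test"),
                              c(length(exp$folds$train[[f]]),
                                length(exp$folds$test[[f]]))))
  }))
  readr::write_csv(assignments, file.path(dir, "folds.csv"), progress = FALSE)
  for (r in exp$fold_results) {
    utils::write.csv(unclass(r$confusion),
                     file.path(dir, sprintf("confusion_fold%d.csv", r$fold)))
    readr::write_csv(r$history,
                     file.path(dir, sprintf("history_fold%d.csv", r$fold)),
                     progress = FALSE)
    jsonlite::write_json(
      list(fold = r$fold, accuracy = r$metrics$accuracy, r_k = r$metrics$r_k,
           by_class = r$metrics$by_class),
      file.path(dir, sprintf("metrics_fold%d.json", r$fold)),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(unclass(exp$pooled_confusion),
                   file.path(dir, "confusion_pooled.csv"))
  jsonlite::write_json(
    list(accuracy = exp$pooled_metrics$accuracy, r_k = exp$pooled_metrics$r_k,
         by_class = exp$pooled_metrics$by_class,
         fold_mean = as.list(exp$fold_mean)),
    file.path(dir, "metrics_pooled.json"), auto_unbox = TRUE, digits = NA)
  writeLines(exp$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.lift_experiment <- function(x, ...) {
  cat(sprintf("<lift_experiment: %s, %d folds, %d trials>\n",
              x$config$model$name, nrow(x$folds), nrow(x$trials)))
  cat(sprintf("  pooled accuracy %.3f, R_K %.3f\n", x$pooled_metrics$accuracy,
              x$pooled_metrics$r_k))
  invisible(x)
}
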