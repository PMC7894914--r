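# broom-style tidiers for the package's result objects.

#' @describeIn metrics_report Tidy per-class metrics of a report.
#' @param x A `lift_metrics` object.
#' @param ... Unused.
#' @export
tidy.lift_metrics <- function(x, ...) x$by_class

#' @describeIn metrics_report One-row summary (accuracy, R_K, n).
#' @export
glance.lift_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, r_k = x$r_k, n = x$n)
}

#' @describeIn confusion_matrix Long tibble of counts (actual, predicted,
#'   n).
#' @param x A `conf_mat`.
#' @param ... Unused.
#' @export
tidy.conf_mat <- function(x, ...) {
  labs <- rownames(x)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(x)))
  tibble::tibble(
    actual = factor(rep(labs, ncol(x)), levels = labs),
    predicted = factor(rep(labs, each = nrow(x)), levels = labs),
    n = as.vector(unclass(x))
  )
}

#' @describeIn train_model Per-epoch training history (epoch, loss,
#'   accuracy).
#' @param x A trained `lift_model`.
#' @param ... Unused.
#' @export
tidy.lift_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history", class = "liftrisk_model_error")
  }
  x$history
}

#' @describeIn train_model One-row summary of a trained model.
#' @export
glance.lift_model <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name,
    n_params = n_params(x),
    trained = isTRUE(x$trained),
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_loss = if (is.null(x$history)) NA_real_ else min(x$history$loss)
  )
}

#' @describeIn run_experiment Per-fold and pooled metrics in long form.
#' @param x A `lift_experiment`.
#' @param ... Unused.
#' @export
tidy.lift_experiment <- function(x, ...) {
  per_fold <- dplyr::bind_rows(lapply(x$fold_results, function(r) {
    tibble::tibble(fold = as.character(r$fold),
                   accuracy = r$metrics$accuracy, r_k = r$metrics$r_k)
  }))
  dplyr::bind_rows(per_fold,
                   tibble::tibble(fold = "pooled",
                                  accuracy = x$pooled_metrics$accuracy,
                                  r_k = x$pooled_metrics$r_k))
}

#' @describeIn run_experiment One-row pooled summary.
#' @export
glance.lift_experiment <- function(x, ...) {
  tibble::tibble(
    model = x$config$model$name,
    n_trials = nrow(x$trials),
    n_folds = nrow(x$folds),
    pooled_accuracy = x$pooled_metrics$accuracy,
    pooled_r_k = x$pooled_metrics$r_k,
    fold_mean_accuracy = x$fold_mean$accuracy,
    fold_mean_r_k = x$fold_mean$r_k
  )
}

#' @describeIn saliency_single Long tibble of saliency weights.
#' @param x A `lift_saliency`.
#' @param ... Unused.
#' @export
tidy.lift_saliency <- function(x, ...) {
  w <- x$weights
  if (x$layout == "sequence") {
    tibble::tibble(channel = rep(channel_layout()$name, ncol(w)),
                   frame = rep(seq_len(ncol(w)), each = nrow(w)),
                   weight = as.vector(w))
  } else {
    tibble::tibble(row = rep(seq_len(nrow(w)), ncol(w)),
                   col = rep(seq_len(ncol(w)), each = nrow(w)),
                   weight = as.vector(w))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
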