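# ggplot2 visualisations for the result objects.

#' @describeIn confusion_matrix Heat-map of the confusion matrix with count
#'   labels.
#' @param object A `conf_mat`.
#' @export
autoplot.conf_mat <- function(object, ...) {
  df <- tidy.conf_mat(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$actual, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted class", y = "Actual class", fill = "Trials") +
    ggplot2::theme_minimal()
}

#' @describeIn train_model Training-loss curve per epoch.
#' @param object A trained `lift_model`.
#' @export
autoplot.lift_model <- function(object, ...) {
  h <- tidy.lift_model(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "Training categorical cross-entropy") +
    ggplot2::theme_minimal()
}

#' @describeIn saliency_single Raster plot of a saliency map (image layout:
#'   95 x 95 cells; sequence layout: channels x frames).
#' @param object A `lift_saliency`.
#' @param ... Unused.
#' @export
autoplot.lift_saliency <- function(object, ...) {
  df <- tidy.lift_saliency(object)
  if (object$layout == "sequence") {
    df$channel <- factor(df$channel, levels = rev(channel_layout()$name))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$channel,
                                          fill = .data$weight)) +
      ggplot2::labs(x = "Frame", y = "Channel")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$weight)) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "Image column", y = "Image row")
  }
  p + ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "|gradient|",
                  title = sprintf("Saliency, %s-risk class (n = %d)",
                                  object$class, object$n_inputs)) +
    ggplot2::theme_minimal()
}

#' Plot one lifting trial's signals
#'
#' Line plot of selected channels over time, faceted by placement.
#'
#' @param trial One row of a trials tibble.
#' @param channels Channel names to include (default: accelerometer x axis
#'   of every placement).
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, channels = NULL) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1)
  layout <- channel_layout()
  if (is.null(channels)) {
    channels <- layout$name[layout$sensor == "acc" & layout$axis == "x"]
  }
  frames <- trial$frames[[1]]
  fs <- trial$sample_rate[1]
  df <- tibble::tibble(
    time = rep(seq_len(nrow(frames)) / fs, length(channels)),
    channel = rep(channels, each = nrow(frames)),
    value = as.vector(frames[, channels])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Signal") +
    ggplot2::theme_minimal()
}
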