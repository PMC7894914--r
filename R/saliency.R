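#' Gradient saliency map for one input
#'
#' Computes the gradient of the class score with respect to the input at
#' the input itself — the first-order answer to "how much would each input
#' element, if changed, move the class score" — and takes elementwise
#' magnitudes. The score is the pre-softmax logit of the class by default
#' (avoids softmax saturation); `score = "post_softmax"` differentiates the
#' softmax probability instead. For image models the 3 axis channels are
#' reduced to a 95 x 95 map (max of absolute values by default); for the
#' sequence model the map is 36 features x 750 frames.
#'
#' @param model A trained `lift_model`.
#' @param input One preprocessed input (dims = model input shape, no sample
#'   axis).
#' @param class Risk level (`"low"`/`"medium"`/`"high"` or index 1-3).
#' @param score Differentiate the pre-softmax logit (default) or the
#'   softmax probability.
#' @param reduce Channel reduction for image maps: `"max"` (default) or
#'   `"sum"` of absolute values.
#' @return A `lift_saliency` object: `weights` (95 x 95 or 36 x 750
#'   non-negative matrix), `raw` (unreduced absolute gradient in input
#'   layout), `class`, `layout`, `n_inputs`.
#' @export
saliency_single <- function(model, input, class,
                            score = c("pre_softmax", "post_softmax"),
                            reduce = c("max", "sum")) {
  score <- match.arg(score)
  reduce <- match.arg(reduce)
  if (!isTRUE(model$trained)) {
    abort("saliency requires a trained model", class = "liftrisk_model_error")
  }
  ci <- as_class_index(class)
  stopifnot(length(ci) == 1L, ci >= 1L, ci <= 3L)
  x <- array(input, dim = c(dim(input), 1L))
  check_input_shape(model, x)
  fwd <- nn_forward(model, x, training = FALSE)
  dlogits <- matrix(0, 1, 3)
  if (score == "pre_softmax") {
    dlogits[1, ci] <- 1
  } else {
    p <- softmax_rows(fwd$out)
    dlogits[1, ] <- p[1, ci] * ((seq_len(3) == ci) - p[1, ])
  }
  g <- nn_backward(model, fwd$caches, dlogits)$dx
  raw <- abs(array(g, dim = dim(input)))
  new_saliency(raw, ci, reduce, n_inputs = 1L)
}

new_saliency <- function(raw, class_index, reduce, n_inputs) {
  if (length(dim(raw)) == 3L) {
    layout <- "image"
    weights <- apply(raw, c(1, 2), if (reduce == "max") max else sum)
  } else {
    layout <- "sequence"
    weights <- t(raw)  # (T, F) gradient -> 36 features x 750 frames
  }
  structure(list(weights = weights, raw = raw,
                 class = risk_levels()[class_index], layout = layout,
                 n_inputs = n_inputs), class = "lift_saliency")
}

#' Class-average saliency over a trial set
#'
#' Mean of the per-trial magnitude maps over all trials whose *true* class
#' is `class`; the average is invariant to trial ordering.
#'
#' @param model A trained `lift_model`.
#' @param x Input batch array (last dimension indexes trials).
#' @param labels True risk labels for the batch.
#' @inheritParams saliency_single
#' @return A `lift_saliency` object averaged over the class members.
#' @export
saliency_class_average <- function(model, x, labels, class,
                                   score = c("pre_softmax", "post_softmax"),
                                   reduce = c("max", "sum")) {
  score <- match.arg(score)
  reduce <- match.arg(reduce)
  ci <- as_class_index(class)
  yi <- as_class_index(labels)
  members <- which(yi == ci)
  if (length(members) == 0) {
    abort(sprintf("no trials with true class %s", risk_levels()[ci]),
          class = "liftrisk_metric_error")
  }
  acc <- NULL
  for (i in members) {
    one <- saliency_single(model, slice_input(x, i), ci, score = score,
                           reduce = reduce)
    acc <- if (is.null(acc)) one$raw else acc + one$raw
  }
  new_saliency(acc / length(members), ci, reduce,
               n_inputs = length(members))
}

slice_input <- function(x, i) {
  d <- dim(x)
  if (length(d) == 4L) array(x[, , , i], dim = d[1:3])
  else array(x[, , i], dim = d[1:2])
}

#' Rank the six IMU placements by saliency mass
#'
#' For a sequence-model map (36 features x 750 frames), each placement's
#' importance is the sum of weights over its 6 rows (accelerometer +
#' gyroscope, 3 axes each) and all frames. Importances therefore sum to the
#' total map mass. Ties keep placement order stable.
#'
#' @param map A `lift_saliency` with sequence layout (or a 36 x 750
#'   matrix).
#' @return Tibble with `placement`, `importance`, `rank`, descending.
#' @export
sensor_importance <- function(map) {
  w <- if (inherits(map, "lift_saliency")) map$weights else map
  if (!is.matrix(w) || nrow(w) != 36L) {
    abort("sensor_importance() needs a 36 x frames sequence saliency map",
          class = "liftrisk_shape_error")
  }
  placements <- unique(channel_layout()$placement)
  imp <- vapply(seq_len(6), function(p) {
    sum(w[((p - 1) * 6 + 1):(p * 6), ])
  }, numeric(1))
  out <- tibble::tibble(placement = placements, importance = imp,
                        order = seq_len(6))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$order)
  out$rank <- seq_len(6)
  dplyr::select(out, "placement", "importance", "rank")
}

#' Per-frame saliency profile
#'
#' Collapses a saliency map to one weight per frame. Sequence maps sum
#' their 36 feature rows per frame; image maps are first decoded back to
#' the 12 x 750 x 3 tensor layout (the encoding is a bijection) and then
#' summed over streams and axes.
#'
#' @param map A `lift_saliency`.
#' @return Tibble with `frame` (1-750) and `weight`.
#' @export
saliency_frame_profile <- function(map) {
  stopifnot(inherits(map, "lift_saliency"))
  if (map$layout == "sequence") {
    w <- colSums(map$weights)
  } else {
    tensor <- decode_image(map$raw)
    w <- apply(tensor, 2, sum)
  }
  tibble::tibble(frame = seq_along(w), weight = w)
}
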