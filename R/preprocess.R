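#' Band-pass filter specification
#'
#' Butterworth band-pass used to strip drift and high-frequency noise from
#' the IMU channels before tensor formation. The default (order-2 prototype,
#' 2-12 Hz passband at 25 Hz sampling) keeps the voluntary-movement band and
#' rejects DC/gravity drift. The band-pass is realised from an order-`order`
#' low-pass prototype (so it has `2 * order` poles), the convention of the
#' common scientific filter-design stacks.
#'
#' @param order Prototype filter order.
#' @param low_cut,high_cut Passband edges in Hz; need
#'   `0 < low_cut < high_cut < sample_rate / 2`.
#' @param sample_rate Sampling rate in Hz.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 2L, low_cut = 2, high_cut = 12,
                        sample_rate = 25) {
  order <- check_positive_int(order, "order")
  low_cut <- check_positive_num(low_cut, "low_cut")
  high_cut <- check_positive_num(high_cut, "high_cut")
  sample_rate <- check_positive_num(sample_rate, "sample_rate")
  if (!(low_cut < high_cut && high_cut < sample_rate / 2)) {
    abort("need 0 < low_cut < high_cut < sample_rate/2 (high_cut at or above Nyquist)",
          class = "liftrisk_config_error")
  }
  structure(list(order = order, low_cut = low_cut, high_cut = high_cut,
                 sample_rate = sample_rate), class = "filter_spec")
}

#' Band-pass filter a multi-channel signal matrix
#'
#' Filters every column independently with the Butterworth band-pass of
#' `spec`. By default the filter is applied forward and backward
#' (zero-phase), so burst positions are not skewed by group delay; set
#' `zero_phase = FALSE` for a single causal pass (streaming use).
#'
#' @param x Numeric matrix, frames x channels.
#' @param spec A [filter_spec()].
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @return Filtered matrix of the same dimensions.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(spec, "filter_spec"), is.matrix(x), is.numeric(x))
  if (nrow(x) <= 3L * spec$order) {
    abort(sprintf("need more than %d frames to filter (got %d)",
                  3L * spec$order, nrow(x)), class = "liftrisk_filter_error")
  }
  nyq <- spec$sample_rate / 2
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  out <- x
  for (ch in seq_len(ncol(x))) {
    out[, ch] <- if (zero_phase) signal::filtfilt(bf, x[, ch])
                 else as.numeric(signal::filter(bf, x[, ch]))
  }
  out
}

#' Band-pass filter every trial in a trials tibble
#'
#' @param trials Trials tibble with a `frames` list-column.
#' @inheritParams bandpass_filter
#' @return The tibble with `frames` replaced by their filtered versions.
#' @export
filter_trials <- function(trials, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(is.data.frame(trials), "frames" %in% names(trials))
  if ("sample_rate" %in% names(trials) &&
      any(trials$sample_rate != spec$sample_rate)) {
    abort("trial sample_rate does not match filter_spec sample_rate",
          class = "liftrisk_config_error")
  }
  trials$frames <- purrr::map(trials$frames, bandpass_filter, spec = spec,
                              zero_phase = zero_phase)
  trials
}

#' Rearrange and zero-pad one trial into a 12 x 750 x 3 tensor
#'
#' The frames x 36 signal matrix becomes a tensor with rows = the 12 sensor
#' streams (placement-major, accelerometer before gyroscope; see
#' [channel_layout()]), columns = frames, and depth = the x/y/z axes. Trials
#' shorter than `max_frames` are zero-extended along the frame axis;
#' `pad_start` records the first padded column. Longer trials raise an error
#' rather than silently truncating.
#'
#' @param frames Numeric matrix, frames x 36.
#' @param max_frames Target frame count (750 = 30 s at 25 Hz).
#' @return List with `data` (12 x `max_frames` x 3 array) and `pad_start`
#'   (number of real frames; padding occupies columns `pad_start + 1` on).
#' @export
pad_tensor <- function(frames, max_frames = 750L) {
  stopifnot(is.matrix(frames), ncol(frames) == 36L)
  n <- nrow(frames)
  if (n > max_frames) {
    abort(sprintf("trial has %d frames, more than max_frames = %d; refusing to truncate",
                  n, max_frames), class = "liftrisk_truncation_error")
  }
  tensor <- array(0, dim = c(12L, max_frames, 3L))
  for (d in 1:3) {
    tensor[, seq_len(n), d] <- t(frames[, (0:11) * 3 + d, drop = FALSE])
  }
  list(data = tensor, pad_start = n)
}

#' Add padded tensors to a trials tibble
#'
#' @param trials Trials tibble with a `frames` list-column.
#' @param max_frames Target frame count.
#' @return The tibble with list-column `tensor` and column `pad_start` added.
#' @export
pad_trials <- function(trials, max_frames = 750L) {
  padded <- purrr::map(trials$frames, pad_tensor, max_frames = max_frames)
  trials$tensor <- purrr::map(padded, "data")
  trials$pad_start <- purrr::map_int(padded, "pad_start")
  trials
}

#' Fit a per-channel scaler on training tensors
#'
#' Fits an affine transform for each of the 36 axis-channels (12 streams x 3
#' axes) over all supplied tensors. `zscore` centres to mean 0 / SD 1;
#' `minmax` maps the training range to `[-1, 1]`. Fit the scaler on the
#' training fold only and apply the same parameters to held-out data (which
#' may then fall outside the nominal bounds). Zero-variance (or
#' zero-range) channels get scale 1 with a warning.
#'
#' @param tensors List of 12 x T x 3 arrays (training fold).
#' @param mode `"zscore"` (default) or `"minmax"`.
#' @return A `channel_scaler` with `mode`, `center` and `scale`
#'   (12 x 3 matrices).
#' @export
fit_scaler <- function(tensors, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(is.list(tensors), length(tensors) >= 1)
  if (mode == "zscore") {
    n_tot <- 0
    s1 <- s2 <- matrix(0, 12, 3)
    for (t in tensors) {
      s1 <- s1 + apply(t, c(1, 3), sum)
      s2 <- s2 + apply(t, c(1, 3), function(v) sum(v^2))
      n_tot <- n_tot + dim(t)[2]
    }
    center <- s1 / n_tot
    scale <- sqrt(pmax(s2 / n_tot - center^2, 0))
  } else {
    lo <- matrix(Inf, 12, 3)
    hi <- matrix(-Inf, 12, 3)
    for (t in tensors) {
      lo <- pmin(lo, apply(t, c(1, 3), min))
      hi <- pmax(hi, apply(t, c(1, 3), max))
    }
    center <- (hi + lo) / 2
    scale <- (hi - lo) / 2
  }
  degenerate <- scale <= .Machine$double.eps^0.5
  if (any(degenerate)) {
    warn(sprintf("%d constant channel(s); scale forced to 1", sum(degenerate)))
    scale[degenerate] <- 1
  }
  structure(list(mode = mode, center = center, scale = scale),
            class = "channel_scaler")
}

#' Apply a fitted channel scaler
#'
#' @param x A 12 x T x 3 tensor or a list of them.
#' @param scaler A fitted [fit_scaler()] object.
#' @param pad_start Optional; if supplied, columns beyond `pad_start` are
#'   reset to exactly 0 after scaling so padding sits at the neutral value.
#' @return Scaled tensor (or list of tensors).
#' @export
apply_scaler <- function(x, scaler, pad_start = NULL) {
  stopifnot(inherits(scaler, "channel_scaler"))
  if (is.list(x) && !is.array(x)) {
    ps <- pad_start
    return(purrr::imap(x, function(t, i) {
      apply_scaler(t, scaler, if (is.null(ps)) NULL else ps[[i]])
    }))
  }
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[1] == 12L,
            dim(x)[3] == 3L)
  out <- x
  for (d in 1:3) {
    out[, , d] <- (x[, , d] - scaler$center[, d]) / scaler$scale[, d]
  }
  if (!is.null(pad_start) && pad_start < dim(x)[2]) {
    out[, (pad_start + 1):dim(x)[2], ] <- 0
  }
  out
}

#' Encode a lift tensor as a near-square image
#'
#' Each axis-channel's 12 x 750 slice is flattened time-major (all 12 stream
#' values at frame 1, then frame 2, ...) and the 9,000-value sequence is
#' wrapped row-by-row into a 95 x 95 grid; the 25 trailing cells of each
#' channel are padding (value 0). Wrapping row-major keeps temporally
#' adjacent samples spatially close within image rows. [decode_image()]
#' inverts the encoding exactly.
#'
#' @param tensor A 12 x 750 x 3 array.
#' @return A 95 x 95 x 3 array with attribute `n_pad_cells = 25`.
#' @export
encode_image <- function(tensor) {
  if (!is.array(tensor) || !identical(dim(tensor), c(12L, 750L, 3L))) {
    abort("encode_image() expects a 12 x 750 x 3 tensor",
          class = "liftrisk_shape_error")
  }
  img <- array(0, dim = c(95L, 95L, 3L))
  for (d in 1:3) {
    v <- c(as.vector(tensor[, , d]), rep(0, 25))
    img[, , d] <- matrix(v, 95L, 95L, byrow = TRUE)
  }
  attr(img, "n_pad_cells") <- 25L
  img
}

#' @rdname encode_image
#' @param image A 95 x 95 x 3 array produced by [encode_image()].
#' @export
decode_image <- function(image) {
  if (!is.array(image) || !identical(dim(image)[1:3], c(95L, 95L, 3L))) {
    abort("decode_image() expects a 95 x 95 x 3 image",
          class = "liftrisk_shape_error")
  }
  tensor <- array(0, dim = c(12L, 750L, 3L))
  for (d in 1:3) {
    v <- as.vector(t(image[, , d]))[seq_len(9000L)]
    tensor[, , d] <- matrix(v, 12L, 750L)
  }
  tensor
}
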