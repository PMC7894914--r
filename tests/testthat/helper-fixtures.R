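# Shared fixtures, built in code. Heavyweight trained models are memoised
# in this environment so several test files can reuse one training run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# The published worked-example confusion matrix (actual rows, predicted
# columns, class order low/medium/high).
reference_confusion <- function() {
  matrix(c(19, 5, 1, 5, 50, 2, 0, 4, 94), 3, 3,
         dimnames = list(actual = c("low", "medium", "high"),
                         predicted = c("low", "medium", "high")))
}

# Small easy-regime trial set for image-model fixtures: strongly separated
# classes, low noise, fixed 12 s lifts so burst windows line up.
easy_trials <- function() {
  memo("easy_trials", function() {
    trials <- simulate_lifts(sim_config(
      n_subjects = 2, trials_per_zone_per_subject = 2,
      duration_range = c(12, 12), class_separation = 6, noise_sd = 0.05,
      seed = 421))
    pad_trials(filter_trials(trials))
  })
}

easy_fold <- function(representation = "image") {
  memo(paste0("easy_fold_", representation), function() {
    trials <- easy_trials()
    folds <- make_folds(trials, n_folds = 1, test_fraction = 0.25, seed = 77)
    build_fold_data(trials, folds[1, ], representation = representation)
  })
}

# The proposed average-pooling model trained briefly on the easy image
# fold; used by the saliency-localisation checks.
trained_img_model <- function() {
  memo("img_model", function() {
    fd <- easy_fold("image")
    model <- build_model(model_spec("proposed_avgpool"), seed = 5)
    model <- train_model(model, fd$x_train, fd$y_train,
                         training_config(max_epochs = 12, batch_size = 12,
                                         seed = 5))
    list(model = model, fold = fd)
  })
}

# Sequence-model fixture: fixed 5 s lifts padded to a 150-frame window
# (scaled-down sequence length so the last-step LSTM readout is not
# dominated by hundreds of padding steps), with a compact
# convolutional-LSTM trained to convergence.
seq_trials <- function() {
  memo("seq_trials", function() {
    trials <- simulate_lifts(sim_config(
      n_subjects = 4, trials_per_zone_per_subject = 3,
      duration_range = c(5, 5), class_separation = 6, noise_sd = 0.05,
      seed = 421))
    pad_trials(filter_trials(trials), max_frames = 150)
  })
}

trained_seq_model <- function() {
  memo("seq_model", function() {
    trials <- seq_trials()
    folds <- make_folds(trials, n_folds = 1, test_fraction = 0.25, seed = 77)
    fd <- build_fold_data(trials, folds[1, ], representation = "sequence")
    spec <- model_spec("cnn_lstm", input_shape = c(150L, 36L),
                       conv_filters = 16L, n_conv = 2L,
                       lstm_units = 32L, n_lstm = 1L)
    model <- build_model(spec, seed = 7)
    model <- train_model(model, fd$x_train, fd$y_train,
                         training_config(learning_rate = 3e-3,
                                         max_epochs = 150, patience = 150,
                                         batch_size = 16, seed = 7))
    list(model = model, fold = fd, test_rows = trials[fd$test, ])
  })
}

# Union of burst-window frames over a set of trial rows.
burst_frames_union <- function(rows, k_sd = 3) {
  sort(unique(unlist(
    lapply(seq_len(nrow(rows)), function(i) burst_windows(rows[i, ], k_sd))
  )))
}

# Fraction of the top-decile saliency mass falling inside the given frames.
top_decile_concentration <- function(weights, frames) {
  top <- weights >= stats::quantile(weights, 0.9)
  inside <- matrix(FALSE, nrow(weights), ncol(weights))
  inside[, frames] <- TRUE
  sum(weights[top & inside]) / sum(weights[top])
}

# Independent analytic magnitude response of the band-pass built from an
# order-n Butterworth low-pass prototype: |H| = 1/sqrt(1 + Q^(2n)) with
# Q = (f^2 - f_lo*f_hi) / (f * (f_hi - f_lo)).
butter_bandpass_gain <- function(f, low, high, order = 2) {
  q <- (f^2 - low * high) / (f * (high - low))
  1 / sqrt(1 + q^(2 * order))
}

# Steady-state amplitude of a (possibly phase-shifted) sinusoid at
# frequency f in a filtered signal, by least-squares projection onto the
# sin/cos pair over a late window clear of transients.
sine_amplitude <- function(y, f, fs, window = seq(round(length(y) * 0.4),
                                                  round(length(y) * 0.9))) {
  tt <- (window - 1) / fs
  basis <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  cf <- stats::lm.fit(basis, y[window])$coefficients
  sqrt(sum(cf^2))
}
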