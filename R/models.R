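#' Architecture specification for the lifting-risk models
#'
#' Five architectures are available. `proposed_avgpool` is the compact
#' VGG-B-style network: three blocks of size-preserving 3x3 ReLU
#' convolutions (32, then 64+64, then 128+128 filters), each followed by
#' 2x2 *average* pooling and dropout, then flatten, a 1024-unit dense
#' layer, batch normalisation, dropout and a 3-way softmax.
#' `vggb_maxpool` is identical except for max pooling. `simple_cnn` is a
#' pooling-free stack of 32/64/128-filter convolutions straight into
#' softmax. `mlp` flattens the image into a 1024-unit ReLU layer with
#' dropout and softmax. `cnn_lstm` treats the 12 x 750 x 3 tensor as a
#' 750-step sequence of 36 features, with 1-D convolutions over time
#' followed by LSTM layers and softmax (DeepConvLSTM family).
#'
#' L2 regularisation (`l2_lambda`) applies solely to the final softmax
#' dense layer's kernel.
#'
#' @param name Architecture name.
#' @param dropout Dropout fraction used by every dropout layer.
#' @param l2_lambda L2 penalty weight on the final dense kernel.
#' @param input_shape Input dimensions excluding the sample axis; defaults
#'   to `c(95, 95, 3)` for image models and `c(750, 36)` (frames x
#'   features) for `cnn_lstm`.
#' @param conv_filters,conv_kernel,n_conv,lstm_units,n_lstm `cnn_lstm`
#'   internals: number/width of 1-D convolutions over time and LSTM stack
#'   size.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name = c("proposed_avgpool", "vggb_maxpool",
                                "simple_cnn", "mlp", "cnn_lstm"),
                       dropout = 0.25, l2_lambda = 1e-5, input_shape = NULL,
                       conv_filters = 64L, conv_kernel = 5L, n_conv = 4L,
                       lstm_units = 128L, n_lstm = 2L) {
  name <- match.arg(name)
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must be in [0, 1)", class = "liftrisk_config_error")
  }
  check_positive_num(l2_lambda, "l2_lambda", strict = FALSE)
  if (is.null(input_shape)) {
    input_shape <- if (name == "cnn_lstm") c(750L, 36L) else c(95L, 95L, 3L)
  }
  drop_layer <- list(type = "dropout", rate = dropout)
  conv <- function(f) list(type = "conv2d", filters = f, kernel = 3L,
                           activation = "relu")
  pool <- function(op) list(type = "pool2d", op = op, size = c(2L, 2L))
  out_layer <- list(type = "dense", units = 3L, activation = "linear",
                    l2 = l2_lambda)
  layers <- switch(name,
    proposed_avgpool = ,
    vggb_maxpool = {
      op <- if (name == "proposed_avgpool") "avg" else "max"
      list(conv(32L), pool(op), drop_layer,
           conv(64L), conv(64L), pool(op), drop_layer,
           conv(128L), conv(128L), pool(op), drop_layer,
           list(type = "flatten"),
           list(type = "dense", units = 1024L, activation = "relu"),
           list(type = "batchnorm"),
           drop_layer,
           out_layer)
    },
    simple_cnn = list(conv(32L), conv(64L), conv(128L),
                      list(type = "flatten"), out_layer),
    mlp = list(list(type = "flatten"),
               list(type = "dense", units = 1024L, activation = "relu"),
               drop_layer,
               out_layer),
    cnn_lstm = {
      convs <- replicate(n_conv,
                         list(type = "conv1d", filters = as.integer(conv_filters),
                              kernel = as.integer(conv_kernel),
                              activation = "relu"),
                         simplify = FALSE)
      lstms <- lapply(seq_len(n_lstm), function(i) {
        list(type = "lstm", units = as.integer(lstm_units),
             return_seq = i < n_lstm)
      })
      c(convs, lstms, list(out_layer))
    }
  )
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, dropout = dropout, l2_lambda = l2_lambda),
            class = "model_spec")
}

#' Build an untrained model from a specification
#'
#' Initialises weights (He initialisation for ReLU layers, Glorot
#' otherwise; LSTM forget-gate bias starts at 1) and batch-norm running
#' statistics.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `lift_model` object (untrained).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  model <- structure(list(
    spec = spec,
    params = nn_init_params(spec$layers, spec$input_shape, seed),
    state = nn_init_state(spec$layers, spec$input_shape),
    trained = FALSE,
    history = NULL
  ), class = "lift_model")
  model
}

#' Number of trainable parameters of a model
#'
#' Counts every entry of every weight array (batch-norm running statistics
#' are state, not parameters).
#'
#' @param model A `lift_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Output shapes of every layer
#'
#' @param model A `lift_model`.
#' @return List of integer shape vectors (sample axis excluded), one per
#'   layer.
#' @export
model_shapes <- function(model) {
  nn_shapes(model$spec$layers, model$spec$input_shape)
}

#' @export
print.lift_model <- function(x, ...) {
  cat(sprintf("<lift_model: %s>%s\n", x$spec$name,
              if (x$trained) " (trained)" else ""))
  cat(sprintf("  input %s, %s parameters\n",
              paste(x$spec$input_shape, collapse = "x"),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

final_dense_key <- function(model) {
  li <- length(model$spec$layers)
  paste0("L", li, ".W")
}

#' Training protocol settings
#'
#' ADAM on categorical cross-entropy with early stopping on the training
#' loss: training halts when the epoch loss has failed to improve by more
#' than `min_delta` for `patience` epochs, and the weights of the
#' best-loss epoch are restored.
#'
#' @param learning_rate ADAM step size (selected value 1e-3).
#' @param batch_size Minibatch size.
#' @param max_epochs Upper cap on epochs (early stopping usually halts
#'   first).
#' @param patience Early-stopping patience in epochs.
#' @param min_delta Minimum loss improvement that resets patience.
#' @param seed Seed for shuffling, dropout and weight initialisation reuse.
#' @param verbose Print per-epoch loss.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 32L,
                            max_epochs = 500L, patience = 10L, min_delta = 0,
                            seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, patience >= 1, min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = check_positive_int(batch_size, "batch_size"),
                 max_epochs = check_positive_int(max_epochs, "max_epochs"),
                 patience = check_positive_int(patience, "patience"),
                 min_delta = min_delta, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "training_config")
}

#' Train a model with ADAM, cross-entropy and early stopping
#'
#' Optimises categorical cross-entropy (plus the L2 penalty on the final
#' dense kernel) by minibatch ADAM. The monitored quantity is the training
#' cross-entropy at the completion of each epoch; no validation split is
#' carved out of the training fold. On stopping, the parameters of the
#' minimum-loss epoch are restored. A non-finite loss aborts with a
#' diagnostic (the unstable-learning-rate regime).
#'
#' @param model An untrained (or trained) `lift_model`.
#' @param x Input batch array; last dimension indexes samples and the
#'   leading dimensions must match the model's input shape.
#' @param y Labels: risk factor/character, or integers 1-3.
#' @param config A [training_config()].
#' @return The trained `lift_model`, with `history` (tibble of epoch, loss,
#'   accuracy) and `best_epoch` filled in.
#' @export
train_model <- function(model, x, y, config = training_config()) {
  stopifnot(inherits(model, "lift_model"), inherits(config, "training_config"))
  check_input_shape(model, x)
  yi <- as_class_index(y)
  n <- n_samples(x)
  stopifnot(length(yi) == n)
  Y <- one_hot(yi)
  lambda <- model$spec$l2_lambda
  wkey <- final_dense_key(model)

  old <- seed_guard(config$seed)
  on.exit(old(), add = TRUE)

  model$params <- deep_copy(model$params)  # ADAM updates in place
  opt <- adam_new(model$params)
  best <- list(loss = Inf, params = deep_copy(model$params),
               state = model$state, epoch = 0L)
  wait <- 0L
  history <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    total_loss <- 0
    total_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1, n)]
      xb <- batch_slice(x, bi)
      yb <- Y[bi, , drop = FALSE]
      fwd <- nn_forward(model, xb, training = TRUE)
      model$state <- fwd$state
      p <- softmax_rows(fwd$out)
      nb <- length(bi)
      ce <- -sum(log(pmax(p[cbind(seq_len(nb), yi[bi])], 1e-12))) / nb
      loss <- ce + lambda * sum(model$params[[wkey]]^2)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite loss at epoch %d; learning rate %.3g is in the unstable regime",
                      epoch, config$learning_rate),
              class = "liftrisk_training_error")
      }
      dlogits <- (p - yb) / nb
      bwd <- nn_backward(model, fwd$caches, dlogits)
      bwd$grads[[wkey]] <- bwd$grads[[wkey]] +
        2 * lambda * model$params[[wkey]]
      step <- adam_step(opt, model$params, bwd$grads, config$learning_rate)
      opt <- step$opt
      model$params <- step$params
      total_loss <- total_loss + loss * nb
      total_correct <- total_correct + sum(argmax_high(p) == yi[bi])
    }
    epoch_loss <- total_loss / n
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss,
                                       accuracy = total_correct / n)
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch, epoch_loss,
                      total_correct / n))
    }
    if (epoch_loss < best$loss - config$min_delta) {
      best <- list(loss = epoch_loss, params = deep_copy(model$params),
                   state = model$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  model$config <- config
  model
}

check_input_shape <- function(model, x) {
  d <- dim(x)
  expected <- model$spec$input_shape
  if (is.null(d) || length(d) != length(expected) + 1L ||
      !all(d[-length(d)] == expected)) {
    abort(sprintf("input shape (%s) does not match model input %s plus a sample axis",
                  paste(d, collapse = "x"), paste(expected, collapse = "x")),
          class = "liftrisk_shape_error")
  }
  invisible(TRUE)
}

#' Predict class probabilities or hard labels
#'
#' Inference is deterministic for fixed weights (dropout off, batch-norm
#' running statistics). Hard labels break probability ties toward the
#' higher risk class, the conservative choice for a safety application.
#'
#' @param object A trained `lift_model`.
#' @param x Input batch array (preprocessed with the training fold's
#'   scaler).
#' @param type `"prob"` for an N x 3 probability matrix, `"class"` for a
#'   risk factor.
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @export
predict.lift_model <- function(object, x, type = c("prob", "class"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  check_input_shape(object, x)
  n <- n_samples(x)
  probs <- matrix(NA_real_, n, 3L,
                  dimnames = list(NULL, risk_levels()))
  for (start in seq(1, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1, n)
    fwd <- nn_forward(object, batch_slice(x, bi), training = FALSE)
    probs[bi, ] <- softmax_rows(fwd$out)
  }
  if (type == "prob") probs
  else factor(risk_levels()[argmax_high(probs)], levels = risk_levels())
}
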