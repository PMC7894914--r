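# Independent layer-arithmetic oracles: shapes by hand-applied pooling
# floor-division, parameter counts from first principles
# (conv: k*k*c_in*c_out + c_out; dense: in*out + out; batch-norm: 2*units;
# lstm: 4u*(f + u + 1)).

test_that("proposed model shape chain and parameter count match the oracle", {
  spec <- model_spec("proposed_avgpool")
  m <- build_model(spec, seed = 1)
  shapes <- model_shapes(m)

  side <- 95
  for (pool in 1:3) side <- side %/% 2          # 95 -> 47 -> 23 -> 11
  expect_equal(side, 11)
  flat_at <- which(vapply(spec$layers, `[[`, "", "type") == "flatten")
  expect_equal(shapes[[flat_at]], 11 * 11 * 128)
  expect_equal(shapes[[flat_at]], 15488)
  expect_equal(shapes[[length(shapes)]], 3)

  count <- (3 * 3 * 3 * 32 + 32) +
    (3 * 3 * 32 * 64 + 64) + (3 * 3 * 64 * 64 + 64) +
    (3 * 3 * 64 * 128 + 128) + (3 * 3 * 128 * 128 + 128) +
    (15488 * 1024 + 1024) + 2 * 1024 + (1024 * 3 + 3)
  expect_equal(n_params(m), count)
})

test_that("comparison models match their independent parameter counts", {
  mlp <- build_model(model_spec("mlp"), seed = 1)
  expect_equal(n_params(mlp),
               (95 * 95 * 3) * 1024 + 1024 + 1024 * 3 + 3)

  cnn <- build_model(model_spec("simple_cnn"), seed = 1)
  expect_equal(n_params(cnn),
               (3 * 3 * 3 * 32 + 32) + (3 * 3 * 32 * 64 + 64) +
                 (3 * 3 * 64 * 128 + 128) + (95 * 95 * 128 * 3 + 3))

  seq <- build_model(model_spec("cnn_lstm", conv_filters = 8, conv_kernel = 5,
                                n_conv = 2, lstm_units = 6, n_lstm = 2),
                     seed = 1)
  expect_equal(n_params(seq),
               (5 * 36 * 8 + 8) + (5 * 8 * 8 + 8) +
                 4 * 6 * (8 + 6 + 1) + 4 * 6 * (6 + 6 + 1) + (6 * 3 + 3))
  # 1-D convolutions preserve the 750-step sequence; LSTM ends at units
  shapes <- model_shapes(seq)
  expect_equal(shapes[[1]], c(750, 8))
  expect_equal(shapes[[3]], c(750, 6))
  expect_equal(shapes[[4]], 6)
})

test_that("max-pool variant differs from the proposed model only in pooling", {
  a <- model_spec("proposed_avgpool")
  b <- model_spec("vggb_maxpool")
  strip_pool <- function(layers) lapply(layers, function(l) {
    if (l$type == "pool2d") l$op <- NULL
    l
  })
  expect_identical(strip_pool(a$layers), strip_pool(b$layers))
  pools <- function(s) unlist(lapply(s$layers, function(l) {
    if (l$type == "pool2d") l$op
  }))
  expect_equal(pools(a), rep("avg", 3))
  expect_equal(pools(b), rep("max", 3))
})

test_that("softmax outputs are normalised and batching-invariant", {
  spec <- model_spec("cnn_lstm", input_shape = c(40L, 6L), conv_filters = 4,
                     n_conv = 1, lstm_units = 5, n_lstm = 1)
  m <- build_model(spec, seed = 2)
  set.seed(9)
  x <- array(rnorm(40 * 6 * 7), c(40, 6, 7))
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  one <- predict(m, array(x[, , 3], c(40, 6, 1)), type = "prob")
  expect_equal(p[3, ], one[1, ], tolerance = 1e-12)
  expect_error(predict(m, array(0, c(40, 5, 2))),
               class = "liftrisk_shape_error")
})

test_that("hard labels break probability ties toward higher risk", {
  expect_equal(liftrisk:::argmax_high(matrix(c(0.4, 0.2, 0.4), 1)), 3)
  expect_equal(liftrisk:::argmax_high(matrix(c(1, 1, 1) / 3, 1)), 3)
  expect_equal(liftrisk:::argmax_high(matrix(c(0.5, 0.3, 0.2), 1)), 1)
})

tiny_training_set <- function(n = 30, d = c(6, 6, 3), seed = 17) {
  set.seed(seed)
  y <- rep(1:3, length.out = n)
  x <- array(rnorm(prod(d) * n, sd = 0.3), c(d, n))
  for (i in seq_len(n)) x[1, 1, , i] <- x[1, 1, , i] + y[i]  # separable cue
  list(x = x, y = y)
}

test_that("early stopping restores the minimum-loss epoch", {
  ts <- tiny_training_set()
  spec <- model_spec("mlp", input_shape = c(6L, 6L, 3L), dropout = 0.4)
  m <- build_model(spec, seed = 4)
  m <- train_model(m, ts$x, ts$y,
                   training_config(max_epochs = 200, patience = 3,
                                   batch_size = 10, seed = 4))
  h <- tidy(m)
  expect_equal(m$best_epoch, which.min(h$loss))
  # stopped within `patience` epochs of the best epoch, before the cap
  expect_lte(nrow(h), m$best_epoch + 3)
  expect_lt(nrow(h), 200)
  expect_equal(min(h$loss), glance(m)$best_loss)
})

test_that("training is reproducible given a seed", {
  ts <- tiny_training_set()
  spec <- model_spec("mlp", input_shape = c(6L, 6L, 3L))
  cfg <- training_config(max_epochs = 5, batch_size = 10, seed = 8)
  m1 <- train_model(build_model(spec, seed = 8), ts$x, ts$y, cfg)
  m2 <- train_model(build_model(spec, seed = 8), ts$x, ts$y, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("a too-high learning rate usually ends at a higher loss", {
  # scaled-down view of the unstable-learning-rate regime: same data and
  # initialisation, ten seed pairs, compare final best losses
  ts <- tiny_training_set(n = 24)
  spec <- model_spec("mlp", input_shape = c(6L, 6L, 3L), dropout = 0)
  worse <- 0L
  for (s in 1:10) {
    m_hi <- train_model(build_model(spec, seed = s), ts$x, ts$y,
                        training_config(learning_rate = 1, max_epochs = 12,
                                        batch_size = 8, seed = s))
    m_lo <- train_model(build_model(spec, seed = s), ts$x, ts$y,
                        training_config(learning_rate = 1e-3, max_epochs = 12,
                                        batch_size = 8, seed = s))
    if (min(m_hi$history$loss) > min(m_lo$history$loss)) worse <- worse + 1L
  }
  expect_gte(worse, 6)
})

test_that("the MLP fits a separable 2-class toy of 40 images perfectly", {
  trials <- simulate_lifts(sim_config(
    n_subjects = 2, trials_per_zone_per_subject = 3,
    duration_range = c(4, 6), class_separation = 5, noise_sd = 0.05,
    seed = 77))
  trials <- pad_trials(filter_trials(trials))
  two <- trials[trials$risk != "medium", ]
  two <- two[seq_len(40), ]
  sc <- fit_scaler(two$tensor)
  imgs <- array(0, c(95, 95, 3, 40))
  for (i in 1:40) {
    imgs[, , , i] <- encode_image(apply_scaler(two$tensor[[i]], sc,
                                               two$pad_start[i]))
  }
  m <- build_model(model_spec("mlp"), seed = 6)
  m <- train_model(m, imgs, two$risk,
                   training_config(max_epochs = 25, patience = 25,
                                   batch_size = 10, seed = 6))
  pred <- predict(m, imgs, type = "class")
  expect_equal(mean(pred == two$risk), 1)
})

test_that("a diverging run aborts with the unstable-rate diagnostic", {
  ts <- tiny_training_set(n = 12)
  spec <- model_spec("mlp", input_shape = c(6L, 6L, 3L), dropout = 0)
  m <- build_model(spec, seed = 2)
  m$params[["L2.W"]][] <- 1e160   # push the loss past overflow
  m$params[["L4.W"]][] <- 1e160
  expect_error(train_model(m, ts$x, ts$y,
                           training_config(max_epochs = 3, batch_size = 6,
                                           seed = 2)),
               class = "liftrisk_training_error")
})

test_that("hyperparameter sweep reports one row per setting, reproducibly", {
  fd <- easy_fold("image")
  small <- list(x_train = fd$x_train[, , , 1:24, drop = FALSE],
                y_train = fd$y_train[1:24],
                x_test = fd$x_test, y_test = fd$y_test)
  grid <- data.frame(alpha = c(1e-3, 3e-4))
  cfg <- training_config(max_epochs = 3, batch_size = 8, seed = 3)
  tab <- suppressWarnings(
    hyperparameter_sweep(list(small), grid, name = "mlp", config = cfg))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("lambda", "alpha", "dropout", "mean_r_k",
                    "mean_accuracy") %in% names(tab)))
  tab2 <- suppressWarnings(
    hyperparameter_sweep(list(small), grid, name = "mlp", config = cfg))
  expect_equal(tab, tab2)
  expect_error(hyperparameter_sweep(list(small), data.frame()),
               class = "liftrisk_config_error")
})
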