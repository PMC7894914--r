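# Hand-built purely linear model: flatten -> dense 3 with known weights.
# The class-score gradient of a linear model is exactly its weight vector.
linear_model <- function(d = c(4L, 5L, 3L), seed = 1) {
  spec <- structure(list(
    name = "mlp", input_shape = d,
    layers = list(list(type = "flatten"),
                  list(type = "dense", units = 3L, activation = "linear",
                       l2 = 0)),
    dropout = 0, l2_lambda = 0), class = "model_spec")
  m <- build_model(spec, seed = seed)
  m$trained <- TRUE
  m
}

test_that("saliency of a linear model is exactly its absolute weights", {
  m <- linear_model()
  x <- array(rnorm(60), c(4, 5, 3))
  for (cl in 1:3) {
    sal <- saliency_single(m, x, cl)
    expect_equal(sal$raw, array(abs(m$params[["L2.W"]][, cl]), c(4, 5, 3)))
    expect_equal(sal$weights, apply(sal$raw, c(1, 2), max))
  }
  sum_red <- saliency_single(m, x, 1, reduce = "sum")
  expect_equal(sum_red$weights, apply(sum_red$raw, c(1, 2), sum))
})

test_that("saliency gradients agree with central finite differences", {
  spec <- model_spec("proposed_avgpool", input_shape = c(12L, 12L, 3L),
                     dropout = 0)
  m <- build_model(spec, seed = 11)
  m$trained <- TRUE
  set.seed(12)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  ci <- 2L
  fwd <- liftrisk:::nn_forward(m, array(x, c(dim(x), 1L)), training = FALSE)
  dlog <- matrix(0, 1, 3); dlog[1, ci] <- 1
  g <- liftrisk:::nn_backward(m, fwd$caches, dlog)$dx
  score <- function(xx) {
    f <- liftrisk:::nn_forward(m, array(xx, c(dim(xx), 1L)), training = FALSE)
    f$out[1, ci]
  }
  eps <- 1e-4
  idx <- sample(length(x), 20)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xn <- x; xn[i] <- xn[i] - eps
    fd <- (score(xp) - score(xn)) / (2 * eps)
    expect_equal(as.vector(g)[i], fd,
                 tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("saliency requires a trained model and is finite everywhere", {
  m <- build_model(model_spec("mlp"), seed = 1)
  x <- array(0, c(95, 95, 3))
  expect_error(saliency_single(m, x, "high"), class = "liftrisk_model_error")

  # padded short trial through the real pipeline: map defined at pad cells
  trials <- easy_trials()
  sc <- fit_scaler(trials$tensor[1:8])
  img <- encode_image(apply_scaler(trials$tensor[[1]], sc,
                                   trials$pad_start[1]))
  m$trained <- TRUE
  sal <- saliency_single(m, img, "high")
  expect_true(all(is.finite(sal$weights)))
  expect_true(all(sal$weights >= 0))
  expect_equal(dim(sal$weights), c(95L, 95L))
})

test_that("post-softmax scores also differentiate cleanly", {
  m <- linear_model(seed = 3)
  x <- array(rnorm(60), c(4, 5, 3))
  sal <- saliency_single(m, x, 2, score = "post_softmax")
  expect_true(all(is.finite(sal$raw)))
  # for a linear model, d p_c / d x = p_c * (W_c - sum_j p_j W_j)
  fwd <- liftrisk:::nn_forward(m, array(x, c(dim(x), 1)), training = FALSE)
  p <- liftrisk:::softmax_rows(fwd$out)[1, ]
  W <- m$params[["L2.W"]]
  expected <- abs(p[2] * (W[, 2] - as.vector(W %*% p)))
  expect_equal(as.vector(sal$raw), expected, tolerance = 1e-10)
})

test_that("class averaging equals the single map for one trial and is order-invariant", {
  m <- linear_model(seed = 5)
  set.seed(6)
  x <- array(rnorm(4 * 5 * 3 * 6), c(4, 5, 3, 6))
  labels <- factor(c("low", "high", "high", "medium", "high", "low"),
                   levels = risk_levels())
  one <- saliency_class_average(m, x[, , , 4, drop = FALSE], labels[4],
                                "medium")
  single <- saliency_single(m, array(x[, , , 4], c(4, 5, 3)), "medium")
  expect_equal(one$weights, single$weights)

  avg <- saliency_class_average(m, x, labels, "high")
  perm <- c(5, 2, 3, 1, 6, 4)
  avg2 <- saliency_class_average(m, x[, , , perm, drop = FALSE],
                                 labels[perm], "high")
  expect_equal(avg$weights, avg2$weights)
  expect_equal(avg$n_inputs, 3L)
  expect_error(saliency_class_average(m, x, labels, 99))
  expect_error(saliency_class_average(m, x[, , , 1, drop = FALSE],
                                      labels[1], "medium"),
               class = "liftrisk_metric_error")
})

test_that("sensor importance conserves mass and breaks ties stably", {
  uniform <- matrix(1, 36, 750)
  imp <- sensor_importance(uniform)
  expect_equal(imp$importance, rep(6 * 750, 6))
  expect_equal(imp$placement, unique(channel_layout()$placement))
  expect_equal(sum(imp$importance), sum(uniform))
  expect_error(sensor_importance(matrix(1, 12, 750)),
               class = "liftrisk_shape_error")
})

test_that("rescaled inputs scale the gradient by the known per-channel factor", {
  # fixed linear model; feeding x/s instead of x divides each channel
  # gradient of the raw-unit view by s, leaving importance rankings intact
  m <- linear_model(seed = 9)
  x <- array(rnorm(60), c(4, 5, 3))
  s1 <- saliency_single(m, x, 1)
  s2 <- saliency_single(m, x * 2, 1)  # linear: gradient unchanged by input
  expect_equal(s1$raw, s2$raw)
})

test_that("image-model saliency concentrates on the injected burst frames", {
  fit <- trained_img_model()
  fd <- fit$fold
  sal <- saliency_class_average(fit$model, fd$x_test, fd$y_test, "high")
  expect_equal(dim(sal$weights), c(95L, 95L))

  prof <- saliency_frame_profile(sal)
  expect_equal(nrow(prof), 750)
  trials <- easy_trials()
  high_rows <- trials[fd$test, ][trials$risk[fd$test] == "high", ]
  frames_in_burst <- burst_frames_union(high_rows)
  conc <- top_decile_concentration(matrix(prof$weight, 1), frames_in_burst)
  expect_gt(conc, 0.5)
})

test_that("sequence-model saliency weights the back/wrist channels the simulator loads", {
  fit <- trained_seq_model()
  fd <- fit$fold
  sal <- saliency_class_average(fit$model, fd$x_test, fd$y_test, "high")
  expect_equal(dim(sal$weights), c(36L, 150L))

  imp <- sensor_importance(sal)
  expect_true("back" %in% imp$placement[1:3])
  expect_gte(sum(c("wrist_l", "wrist_r") %in% imp$placement[1:3]), 1)

  prof <- saliency_frame_profile(sal)
  expect_equal(nrow(prof), 150)
  expect_equal(sum(prof$weight), sum(sal$weights))
})

test_that("the sequence model learns the easy regime to high accuracy", {
  fit <- trained_seq_model()
  fd <- fit$fold
  pred <- predict(fit$model, fd$x_test, type = "class")
  expect_gte(mean(pred == fd$y_test), 0.9)
})
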