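test_that("filter specification enforces the passband ordering and Nyquist", {
  expect_error(filter_spec(high_cut = 13), class = "liftrisk_config_error")
  expect_error(filter_spec(low_cut = 12, high_cut = 2),
               class = "liftrisk_config_error")
  expect_silent(filter_spec())
})

test_that("band-pass rejects DC, passes zeros, and is linear", {
  spec <- filter_spec()
  n <- 500
  zeros <- matrix(0, n, 2)
  expect_equal(bandpass_filter(zeros, spec), zeros)

  dc <- matrix(5, n, 1)
  out <- bandpass_filter(dc, spec)
  core <- out[100:400, 1]  # clear of edge transients
  expect_lt(max(abs(core)), 0.01 * 5)

  set.seed(1)
  x1 <- matrix(rnorm(n), n, 1)
  x2 <- matrix(rnorm(n), n, 1)
  lhs <- bandpass_filter(2 * x1 + 3 * x2, spec)
  rhs <- 2 * bandpass_filter(x1, spec) + 3 * bandpass_filter(x2, spec)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("steady-state gain matches the analytic Butterworth response", {
  spec <- filter_spec()
  fs <- spec$sample_rate
  n <- 30 * fs
  tt <- (seq_len(n) - 1) / fs
  for (f in c(5, 6, 7)) {
    x <- matrix(sin(2 * pi * f * tt), n, 1)
    single <- bandpass_filter(x, spec, zero_phase = FALSE)
    gain <- sine_amplitude(single[, 1], f, fs)
    expect_equal(gain, butter_bandpass_gain(f, 2, 12), tolerance = 0.02)
    # forward-backward filtering applies the magnitude twice
    zp <- bandpass_filter(x, spec, zero_phase = TRUE)
    expect_equal(sine_amplitude(zp[, 1], f, fs),
                 butter_bandpass_gain(f, 2, 12)^2, tolerance = 0.02)
  }
})

test_that("padding rearranges channels and zero-extends, refusing truncation", {
  set.seed(4)
  frames <- matrix(rnorm(300 * 36), 300, 36)
  lt <- pad_tensor(frames, 750)
  expect_equal(dim(lt$data), c(12L, 750L, 3L))
  expect_equal(lt$pad_start, 300)
  expect_true(all(lt$data[, 301:750, ] == 0))
  # stream s, axis d holds column (s-1)*3 + d
  for (s in c(1, 7, 12)) for (d in 1:3) {
    expect_equal(lt$data[s, 1:300, d], unname(frames[, (s - 1) * 3 + d]))
  }

  full <- pad_tensor(matrix(rnorm(750 * 36), 750, 36), 750)
  expect_equal(full$pad_start, 750)

  expect_error(pad_tensor(matrix(0, 800, 36), 750),
               class = "liftrisk_truncation_error")
})

test_that("z-score scaler centres every channel on the training set only", {
  set.seed(5)
  tensors <- replicate(6, array(rnorm(12 * 100 * 3, mean = 2, sd = 3),
                                c(12, 100, 3)), simplify = FALSE)
  sc <- fit_scaler(tensors, "zscore")
  scaled <- apply_scaler(tensors, sc)
  for (d in 1:3) {
    vals <- sapply(scaled, function(t) t[, , d])  # 1200 x 6 per row-channel
    m <- rowMeans(matrix(unlist(lapply(scaled, function(t) t[, , d])), 12))
    expect_true(all(abs(m) < 1e-9))
  }
  pooled <- lapply(1:12, function(s) {
    unlist(lapply(scaled, function(t) t[s, , 1]))
  })
  expect_true(all(abs(vapply(pooled, mean, numeric(1))) < 1e-9))
  sds <- vapply(pooled, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  expect_true(all(abs(sds - 1) < 1e-9))
})

test_that("constant channels scale to zero with a warning", {
  t1 <- array(rnorm(12 * 50 * 3), c(12, 50, 3))
  t1[3, , 2] <- 7
  expect_warning(sc <- fit_scaler(list(t1), "zscore"), "constant")
  out <- apply_scaler(t1, sc)
  expect_true(all(out[3, , 2] == 0))
})

test_that("min-max scaling bounds training data but not held-out data", {
  set.seed(6)
  train <- replicate(4, array(rnorm(12 * 80 * 3), c(12, 80, 3)),
                     simplify = FALSE)
  test <- array(rnorm(12 * 80 * 3, sd = 3), c(12, 80, 3))
  sc <- fit_scaler(train, "minmax")
  strain <- apply_scaler(train, sc)
  expect_true(all(vapply(strain, function(t) max(abs(t)), numeric(1)) <= 1 + 1e-12))
  stest <- apply_scaler(test, sc)
  expect_gt(max(abs(stest)), 1)  # same parameters, so test may exceed bounds
})

test_that("padding reset puts pad columns at exactly zero after scaling", {
  set.seed(7)
  t1 <- array(rnorm(12 * 750 * 3, mean = 5), c(12, 750, 3))
  sc <- fit_scaler(list(t1), "zscore")
  out <- apply_scaler(t1, sc, pad_start = 200)
  expect_true(all(out[, 201:750, ] == 0))
  expect_false(any(out[, 1:200, ] == 0))
})

test_that("image encoding is the exact documented index map and a bijection", {
  set.seed(8)
  tensor <- array(rnorm(27000), c(12, 750, 3))
  img <- encode_image(tensor)
  expect_equal(dim(img), c(95L, 95L, 3L))
  expect_identical(decode_image(img), tensor)

  # non-pad cell count per the 27,000-feature identity
  expect_equal(3 * (95 * 95 - attr(img, "n_pad_cells")), 27000)

  # independent index-arithmetic oracle over every position, every channel:
  # value at (stream s, frame f, axis d), flattened index c0 = s + 12 f
  # (0-based), lands at image row floor(c0/95), column c0 mod 95.
  for (d in 1:3) {
    probe <- array(0, c(12, 750, 3))
    probe[, , d] <- matrix(seq_len(9000) - 1, 12, 750)  # value = s + 12 f
    pimg <- encode_image(probe)
    c0 <- seq_len(9000) - 1
    expect_equal(pimg[cbind(c0 %/% 95 + 1, c0 %% 95 + 1, d)], c0)
    expect_equal(sum(pimg[, , d] != 0), 9000 - 1)  # value 0 sits at cell 1
  }

  # value multiset preserved per channel, padding cells excluded
  for (d in 1:3) {
    expect_equal(sort(as.vector(t(img[, , d]))[1:9000]),
                 sort(as.vector(tensor[, , d])))
  }

  expect_error(encode_image(array(0, c(12, 100, 3))),
               class = "liftrisk_shape_error")
  expect_error(decode_image(array(0, c(94, 95, 3))),
               class = "liftrisk_shape_error")
})

test_that("filter_trials rejects mismatched sample rates", {
  trials <- simulate_lifts(sim_config(n_subjects = 1,
                                      trials_per_zone_per_subject = 1,
                                      duration_range = c(2, 3), seed = 9))
  expect_error(filter_trials(trials, filter_spec(sample_rate = 50,
                                                 high_cut = 20)),
               class = "liftrisk_config_error")
  filtered <- filter_trials(trials)
  expect_equal(dim(filtered$frames[[1]]), dim(trials$frames[[1]]))
})
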