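#' Channel layout of a lifting trial
#'
#' A lifting trial carries 36 signal channels: 6 IMU placements, each with a
#' tri-axial accelerometer and a tri-axial gyroscope. Columns are ordered
#' placement-major, then sensor (accelerometer before gyroscope), then axis
#' (x, y, z), so column `(p-1)*6 + (s-1)*3 + d` holds placement `p`, sensor
#' `s`, axis `d`. The 12 sensor *streams* (placement x sensor) index the rows
#' of the preprocessed 12 x 750 x 3 tensor in the same order.
#'
#' @return A tibble with one row per signal column: `column`, `name`,
#'   `placement`, `sensor`, `axis`, and the tensor row `stream`.
#' @export
#' @examples
#' channel_layout()
channel_layout <- function() {
  placements <- c("back", "wrist_l", "wrist_r", "upper_arm", "waist", "thigh")
  sensors <- c("acc", "gyr")
  axes <- c("x", "y", "z")
  grid <- expand.grid(axis = axes, sensor = sensors, placement = placements,
                      stringsAsFactors = FALSE)[, 3:1]
  tibble::tibble(
    column = seq_len(nrow(grid)),
    name = paste(grid$placement, grid$sensor, grid$axis, sep = "_"),
    placement = grid$placement,
    sensor = grid$sensor,
    axis = grid$axis,
    stream = rep(seq_len(12L), each = 3L)
  )
}

lift_channel_names <- function() channel_layout()$name

#' Simulation settings for synthetic lifting trials
#'
#' Defaults reproduce the study conditions of the motivating NIOSH-style
#' protocol: 10 subjects each performing 6 lifts in all 12 ACGIH zones
#' (720 trials), sampled at 25 Hz, trials capped at 30 s with most lasting
#' 10-15 s.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_zone_per_subject Lifts per subject in each zone.
#' @param sample_rate Sampling rate in Hz.
#' @param max_duration Maximum trial duration in seconds.
#' @param duration_range Length-2 vector; trial durations are drawn uniformly
#'   from this range (seconds). Must lie within `(0, max_duration]`.
#' @param noise_sd Standard deviation of the additive white sensor noise, in
#'   signal units (the burst carrier has unit base amplitude).
#' @param class_separation Non-negative scalar controlling how strongly the
#'   three risk classes' burst amplitudes differ; 0 makes the classes
#'   statistically identical.
#' @param seed Integer seed; the generated set is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10L, trials_per_zone_per_subject = 6L,
                       sample_rate = 25, max_duration = 30,
                       duration_range = c(10, 15), noise_sd = 0.15,
                       class_separation = 1, seed = 1L) {
  cfg <- list(
    n_subjects = check_positive_int(n_subjects, "n_subjects"),
    trials_per_zone_per_subject =
      check_positive_int(trials_per_zone_per_subject,
                         "trials_per_zone_per_subject"),
    sample_rate = check_positive_num(sample_rate, "sample_rate"),
    max_duration = check_positive_num(max_duration, "max_duration"),
    duration_range = duration_range,
    noise_sd = check_positive_num(noise_sd, "noise_sd", strict = FALSE),
    class_separation = check_positive_num(class_separation, "class_separation",
                                          strict = FALSE),
    seed = check_positive_int(abs(seed) + 1L, "seed") - 1L
  )
  if (length(duration_range) != 2L || !is.numeric(duration_range) ||
      any(is.na(duration_range)) || duration_range[1] > duration_range[2] ||
      duration_range[1] <= 0 || duration_range[2] > cfg$max_duration) {
    abort("`duration_range` must be an increasing pair within (0, max_duration]",
          class = "liftrisk_config_error")
  }
  cfg$duration_range <- as.numeric(duration_range)
  structure(cfg, class = "sim_config")
}

# Per-placement base burst amplitudes. Back and both wrists dominate;
# upper arm, waist and thigh carry weaker signal. The class gain multiplies
# the strong placements fully and the weak placements at a quarter rate, so
# the class signature is concentrated on the back/wrist channels.
placement_profile <- function() {
  list(base = c(back = 1.0, wrist_l = 0.9, wrist_r = 0.9,
                upper_arm = 0.5, waist = 0.45, thigh = 0.35),
       strong = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
       sensor = c(acc = 1.0, gyr = 0.7),
       axis = c(x = 1.0, y = 0.8, z = 0.6))
}

#' Generate synthetic lifting trials
#'
#' Each trial is baseline white noise plus two Gaussian-windowed oscillatory
#' bursts: an object-pickup burst near the start of the trial and a
#' return-to-upright burst near the end. Burst amplitude across the six
#' placements depends on the risk class of the trial's zone (back and wrist
#' channels scale most strongly with class), so the class signal and its
#' temporal location are both known ground truth for downstream tests.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per trial: `trial_id`, `subject_id`, `zone`,
#'   `risk`, `duration` (s), `n_frames`, `sample_rate`, `burst_centers`
#'   (list-column, frame indices of the two burst centres), `burst_width`
#'   (Gaussian SD in frames), and `frames` (list-column of `n_frames` x 36
#'   signal matrices, columns per [channel_layout()]).
#' @export
#' @examples
#' trials <- simulate_lifts(sim_config(n_subjects = 1, seed = 7))
#' nrow(trials) # 1 subject x 12 zones x 6 trials
simulate_lifts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  prof <- placement_profile()
  layout <- channel_layout()
  ch_base <- prof$base[layout$placement] * prof$sensor[layout$sensor] *
    prof$axis[layout$axis]
  ch_strong <- prof$strong[match(layout$placement, names(prof$base))]
  burst_freq <- c(4.5, 5.5)     # Hz carriers, inside the 2-12 Hz passband
  width_s <- 0.5                # Gaussian SD of each burst, seconds

  old <- seed_guard(config$seed)
  on.exit(old(), add = TRUE)

  rows <- list()
  id <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (zone in 1:12) {
      k <- as.integer(zone_to_risk(zone))
      gain <- ifelse(ch_strong,
                     1 + config$class_separation * (k - 1),
                     1 + 0.25 * config$class_separation * (k - 1))
      for (trial in seq_len(config$trials_per_zone_per_subject)) {
        id <- id + 1L
        dur <- runif(1, config$duration_range[1], config$duration_range[2])
        n_frames <- max(2L, round(dur * fs))
        tt <- seq_len(n_frames)
        centers <- round(c(0.18, 0.82) * n_frames +
                           rnorm(2, 0, 0.015 * n_frames))
        centers <- pmin(pmax(centers, 2L), n_frames - 1L)
        width <- max(2, round(width_s * fs))
        amp_jit <- exp(rnorm(2, 0, 0.05))
        env <- vapply(seq_len(2), function(bi) {
          exp(-(tt - centers[bi])^2 / (2 * width^2))
        }, numeric(n_frames))
        mat <- matrix(rnorm(n_frames * 36L, 0, config$noise_sd),
                      n_frames, 36L, dimnames = list(NULL, layout$name))
        for (ch in seq_len(36L)) {
          a <- ch_base[ch] * gain[ch]
          for (bi in seq_len(2)) {
            phase <- runif(1, 0, 2 * pi)
            mat[, ch] <- mat[, ch] + a * amp_jit[bi] * env[, bi] *
              sin(2 * pi * burst_freq[bi] * (tt - 1) / fs + phase)
          }
        }
        rows[[id]] <- tibble::tibble(
          trial_id = id,
          subject_id = sprintf("S%02d", subj),
          zone = zone,
          duration = dur,
          n_frames = n_frames,
          sample_rate = fs,
          burst_centers = list(as.integer(centers)),
          burst_width = as.integer(width),
          frames = list(mat)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$risk <- zone_to_risk(out$zone)
  dplyr::relocate(out, "risk", .after = "zone")
}

# Seed the R RNG and return a restore function, so simulation does not
# disturb the caller's RNG stream.
seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_seed) assign(".Random.seed", saved, envir = globalenv())
  }
}

#' Frame windows of the injected bursts
#'
#' Returns, for one simulated trial, the frame indices covered by the two
#' injected bursts (centre +/- `k_sd` Gaussian SDs), clipped to the trial
#' length. Ground truth for saliency-localisation checks.
#'
#' @param trial One row of the tibble returned by [simulate_lifts()].
#' @param k_sd Half-width of each window in burst SDs.
#' @return Integer vector of frame indices (union of the two windows).
#' @export
burst_windows <- function(trial, k_sd = 3) {
  centers <- trial$burst_centers[[1]]
  width <- trial$burst_width[1]
  n <- trial$n_frames[1]
  idx <- unlist(lapply(centers, function(ct) {
    seq(max(1L, floor(ct - k_sd * width)), min(n, ceiling(ct + k_sd * width)))
  }))
  sort(unique(as.integer(idx)))
}
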