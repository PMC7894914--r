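#' Write lifting trials to a directory of CSV files
#'
#' One CSV per trial (header = the 36 channel names, one row per frame) plus
#' a `manifest.csv` listing subject, zone, risk, duration, frame count,
#' sample rate and the relative file path of every trial.
#'
#' @param trials Trials tibble from [simulate_lifts()] or [read_trials()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(is.data.frame(trials), all(c("zone", "frames") %in% names(trials)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("trial_%05d.csv", seq_len(nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    readr::write_csv(tibble::as_tibble(trials$frames[[i]]),
                     file.path(dir, paths[i]), progress = FALSE)
  }
  manifest <- tibble::tibble(
    trial_id = trials$trial_id,
    subject_id = trials$subject_id,
    zone = trials$zone,
    risk = as.character(trials$risk),
    duration = trials$duration,
    n_frames = trials$n_frames,
    sample_rate = trials$sample_rate,
    path = paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Read lifting trials from a directory written by [write_trials()]
#'
#' Validates the manifest and every trial file: all 36 channel columns must
#' be present and numeric, and zones must lie in 1-12. Violations raise a
#' parse error naming the offending file.
#'
#' @param dir Directory containing `manifest.csv` and trial CSV files.
#' @return A trials tibble (as from [simulate_lifts()], without the
#'   simulator-only burst ground-truth columns).
#' @export
read_trials <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest.csv in %s", dir), class = "liftrisk_parse_error")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  bad_zone <- which(!(manifest$zone %in% 1:12))
  if (length(bad_zone) > 0) {
    abort(sprintf("%s line %d: zone %s outside 1-12", manifest_path,
                  bad_zone[1] + 1L, manifest$zone[bad_zone[1]]),
          class = "liftrisk_parse_error")
  }
  wanted <- lift_channel_names()
  frames <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fp <- file.path(dir, manifest$path[i])
    df <- readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(wanted, names(df))
    if (length(missing) > 0) {
      abort(sprintf("%s: missing channel column(s) %s", fp,
                    paste(head(missing, 3), collapse = ", ")),
            class = "liftrisk_parse_error")
    }
    non_num <- wanted[!vapply(df[wanted], is.numeric, logical(1))]
    if (length(non_num) > 0) {
      abort(sprintf("%s: non-numeric values in column %s", fp, non_num[1]),
            class = "liftrisk_parse_error")
    }
    frames[[i]] <- as.matrix(df[wanted])
  }
  out <- tibble::tibble(
    trial_id = manifest$trial_id,
    subject_id = manifest$subject_id,
    zone = manifest$zone,
    risk = factor(manifest$risk, levels = risk_levels()),
    duration = manifest$duration,
    n_frames = manifest$n_frames,
    sample_rate = manifest$sample_rate,
    burst_centers = rep(list(NULL), nrow(manifest)),
    burst_width = NA_integer_,
    frames = frames
  )
  out
}
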