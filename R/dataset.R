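#' Map ACGIH lifting zones to relative risk levels
#'
#' The 12 ACGIH TLV lifting zones collapse onto three risk levels following
#' the Los Alamos-derived simplification: zones 4-5 are low risk, 6-9 medium,
#' and 1-3 plus 10-12 high. With balanced zones this yields the 1:2:3
#' low:medium:high class ratio.
#'
#' @param zone Integer vector of zones in 1-12.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' zone_to_risk(c(5, 7, 10))
zone_to_risk <- function(zone) {
  if (!is.numeric(zone) || any(is.na(zone)) || any(zone < 1 | zone > 12) ||
      any(zone != as.integer(zone))) {
    abort("`zone` must contain integers in 1-12", class = "liftrisk_domain_error")
  }
  map <- rep(NA_character_, 12)
  map[c(4, 5)] <- "low"
  map[6:9] <- "medium"
  map[c(1:3, 10:12)] <- "high"
  factor(map[as.integer(zone)], levels = risk_levels())
}

#' Build per-zone stratified Monte-Carlo cross-validation folds
#'
#' Each fold is an independent stratified random subsample: within every
#' ACGIH zone, a fixed quota of trials is drawn without replacement into the
#' test side and the rest train, so every zone is guaranteed on both sides
#' of every fold. Per-zone test quotas are the largest-remainder rounding of
#' `test_fraction` x zone size, so the global test fraction is hit exactly
#' whenever possible. Folds are independent draws, not a partition.
#'
#' @param trials Trials tibble (needs a `zone` column; rows are indexed
#'   1..n in fold index sets).
#' @param n_folds Number of folds.
#' @param test_fraction Fraction of each zone assigned to the test side.
#' @param seed Integer seed; folds are deterministic given the seed.
#' @param by_subject If `TRUE`, sampling units within each zone are whole
#'   subjects rather than trials (every trial of a sampled subject goes to
#'   the test side). Default `FALSE`: trial-wise sampling.
#' @return A tibble with columns `fold`, `train`, `test` (list-columns of
#'   integer row indices into `trials`) and `seed`.
#' @export
make_folds <- function(trials, n_folds = 4L, test_fraction = 0.25, seed = 1L,
                       by_subject = FALSE) {
  stopifnot(is.data.frame(trials), "zone" %in% names(trials))
  n_folds <- check_positive_int(n_folds, "n_folds")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1)", class = "liftrisk_config_error")
  }
  zones <- sort(unique(trials$zone))
  missing_zones <- setdiff(1:12, zones)
  if (length(missing_zones) > 0) {
    abort(sprintf("zones with no trials: %s",
                  paste(missing_zones, collapse = ", ")),
          class = "liftrisk_fold_error")
  }
  n_zone <- vapply(zones, function(z) sum(trials$zone == z), integer(1))
  if (any(n_zone < 2)) {
    abort("every zone needs at least 2 trials to split",
          class = "liftrisk_fold_error")
  }
  quota <- largest_remainder_round(test_fraction * n_zone,
                                   round(test_fraction * nrow(trials)))
  quota <- pmin(pmax(quota, 1L), n_zone - 1L)  # both sides non-empty per zone

  old <- seed_guard(seed)
  on.exit(old(), add = TRUE)
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- integer(0)
    for (zi in seq_along(zones)) {
      idx <- which(trials$zone == zones[zi])
      if (by_subject) {
        subj <- unique(trials$subject_id[idx])
        n_test_subj <- max(1L, round(quota[zi] / (n_zone[zi] / length(subj))))
        n_test_subj <- min(n_test_subj, length(subj) - 1L)
        pick <- sample(subj, n_test_subj)
        test <- c(test, idx[trials$subject_id[idx] %in% pick])
      } else {
        test <- c(test, sample(idx, quota[zi]))
      }
    }
    test <- sort(test)
    tibble::tibble(fold = f, train = list(setdiff(seq_len(nrow(trials)), test)),
                   test = list(test))
  })
  out <- dplyr::bind_rows(folds)
  out$seed <- seed
  out
}
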