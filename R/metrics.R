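#' Confusion matrix with actual rows and predicted columns
#'
#' @param actual,predicted Equal-length label vectors (risk
#'   factors/characters or 1-based integer class indices).
#' @param k Number of classes.
#' @param labels Class names in fixed order (low, medium, high by default).
#' @return A `k` x `k` integer matrix of class `conf_mat`; rows are actual
#'   classes, columns predicted.
#' @export
#' @examples
#' confusion_matrix(c("low", "high", "high"), c("low", "medium", "high"))
confusion_matrix <- function(actual, predicted, k = 3L,
                             labels = risk_levels()[seq_len(k)]) {
  a <- as_class_index(actual)
  p <- as_class_index(predicted)
  if (length(a) != length(p)) {
    abort("`actual` and `predicted` must have equal length",
          class = "liftrisk_metric_error")
  }
  if (any(a < 1 | a > k) || any(p < 1 | p > k)) {
    abort(sprintf("labels out of range 1-%d", k),
          class = "liftrisk_metric_error")
  }
  C <- matrix(0L, k, k, dimnames = list(actual = labels, predicted = labels))
  for (i in seq_along(a)) C[a[i], p[i]] <- C[a[i], p[i]] + 1L
  structure(C, class = c("conf_mat", "matrix"))
}

as_conf_mat <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C) || any(C < 0)) {
    abort("expected a square non-negative count matrix",
          class = "liftrisk_metric_error")
  }
  C
}

#' Per-class precision, recall and F-measure plus overall statistics
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F-measure = their
#' harmonic mean; overall accuracy = trace / total; plus the Gorodkin
#' multiclass correlation [r_k()]. Divisions by zero yield 0 with a
#' warning. Values are kept at full precision; round for display.
#'
#' @param C Confusion matrix (actual rows x predicted columns).
#' @return A `lift_metrics` object: list with `by_class` tibble (class, tp,
#'   fp, fn, precision, recall, f_measure), `accuracy`, `r_k`, `n`.
#' @export
metrics_report <- function(C) {
  C <- as_conf_mat(C)
  total <- sum(C)
  if (total == 0) {
    abort("empty confusion matrix", class = "liftrisk_metric_error")
  }
  k <- nrow(C)
  tp <- unname(diag(C))
  fp <- unname(colSums(C)) - tp
  fn <- unname(rowSums(C)) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) warn(sprintf("%s undefined for some class; reported as 0", what))
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f <- safe_div(2 * precision * recall, precision + recall, "F-measure")
  by_class <- tibble::tibble(
    class = if (!is.null(rownames(C))) rownames(C) else as.character(seq_len(k)),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = precision, recall = recall, f_measure = f
  )
  structure(list(by_class = by_class, accuracy = sum(tp) / total,
                 r_k = r_k(C), n = total), class = "lift_metrics")
}

#' @export
print.lift_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Accuracy %.*f, R_K %.*f (n = %d)\n", digits, x$accuracy,
              digits, x$r_k, x$n))
  print(dplyr::mutate(x$by_class,
                      dplyr::across(c("precision", "recall", "f_measure"),
                                    ~ round(.x, digits))))
  invisible(x)
}

#' Gorodkin multiclass correlation from a confusion matrix
#'
#' The discretised R_K statistic, the multiclass generalisation of the
#' Matthews/Pearson correlation, computed directly from the count matrix:
#' with `c = trace`, `s = total`, `t_k` the actual (row) totals and `p_k`
#' the predicted (column) totals,
#' `R_K = (c*s - sum(t*p)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))`.
#' Values lie in `[-1, 1]`; by convention 0.7 and above is considered
#' satisfactory agreement. When only a single class was observed or
#' predicted a denominator factor is 0; the degenerate value 0 is returned
#' with a warning.
#'
#' @param C Confusion matrix (actual rows x predicted columns).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
#' @examples
#' r_k(diag(c(5, 5, 5))) # perfect agreement: 1
r_k <- function(C) {
  C <- as_conf_mat(C)
  s <- sum(C)
  if (s == 0) abort("empty confusion matrix", class = "liftrisk_metric_error")
  cc <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- cc * s - sum(t_k * p_k)
  d1 <- s^2 - sum(p_k^2)
  d2 <- s^2 - sum(t_k^2)
  if (d1 <= 0 || d2 <= 0) {
    warn("degenerate confusion matrix (single observed or predicted class); R_K reported as 0")
    return(0)
  }
  num / sqrt(d1 * d2)
}
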