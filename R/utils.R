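# Internal helpers shared across modules.

# Round a non-negative numeric vector to integers that sum to `total`,
# assigning the leftover units to the entries with the largest fractional
# parts (ties broken by position). Used for per-zone test quotas and for
# rescaling the pooled confusion matrix to a single test-set size.
largest_remainder_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  base <- floor(x)
  short <- total - sum(base)
  if (short < 0) {
    # total below the floor sum: take units back from the smallest fractions
    ord <- order(x - base, seq_along(x))
    take <- ord[seq_len(-short)]
    base[take] <- base[take] - 1L
  } else if (short > 0) {
    ord <- order(-(x - base), seq_along(x))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  }
  as.integer(base)
}

one_hot <- function(y, k = length(risk_levels())) {
  y <- as.integer(y)
  stopifnot(all(y >= 1L), all(y <= k))
  out <- matrix(0, length(y), k)
  out[cbind(seq_along(y), y)] <- 1
  out
}

# Coerce labels (factor / character risk levels, or 1-based integers) to
# integer class indices in the fixed low < medium < high order.
as_class_index <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    idx <- match(y, risk_levels())
    if (anyNA(idx)) {
      abort(paste0("unknown risk label(s): ",
                   paste(unique(y[is.na(idx)]), collapse = ", ")),
            class = "liftrisk_label_error")
    }
    return(idx)
  }
  as.integer(y)
}

check_positive_int <- function(value, field) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      value < 1 || value != as.integer(value)) {
    abort(sprintf("`%s` must be a positive integer, got %s", field,
                  deparse(value)), class = "liftrisk_config_error")
  }
  as.integer(value)
}

check_positive_num <- function(value, field, strict = TRUE) {
  ok <- length(value) == 1L && is.numeric(value) && !is.na(value) &&
    (if (strict) value > 0 else value >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a %s number, got %s", field,
                  if (strict) "positive" else "non-negative", deparse(value)),
          class = "liftrisk_config_error")
  }
  as.numeric(value)
}

# Argmax with ties broken toward the higher (riskier) class index.
argmax_high <- function(p) {
  apply(p, 1L, function(row) max(which(row == max(row))))
}
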