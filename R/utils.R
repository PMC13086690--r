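# Internal helpers shared across modules.

# Centered moving average; window in samples, window <= 1 is a no-op.
# Shrinks the window symmetrically at the edges rather than padding.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("mothvis_domain_error", "mothvis_error")))
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0) {
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(value)
}

check_nonnegative <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0) {
    stop_domain(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(value)
}

# Round to 3 significant figures, the precision used in printed reports.
report_signif <- function(x) signif(x, 3)
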