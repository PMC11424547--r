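# Small shared helpers. Kept internal.

# Round half away from zero, the convention used when printing percentages
# in published FAERS summary tables (so 0.565055 -> 56.51 at 2 dp).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of `n` over `total`, rounded half-up to 2 decimals.
pct2 <- function(n, total) {
  if (total == 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total, 2)
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "faersignal_config_error")
}

stop_schema <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "faersignal_schema_error")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config("`%s` must be numeric in [0, 1]", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_config("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# Sample categorical labels from a named probability vector, renormalising.
sample_cat <- function(n, probs) {
  probs <- probs / sum(probs)
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}
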