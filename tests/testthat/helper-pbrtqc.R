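# Shared fixtures, built in code.

# Fixed-width layout with known geometry for hand-checked metric tests.
fixed_layout <- function(n_total, starts, lengths) {
  structure(list(n_total = as.integer(n_total),
                 starts = as.integer(starts),
                 lengths = as.integer(lengths)),
            class = "segment_layout")
}

# Bare control limits for driving detect_alarms() directly.
fake_limits <- function(ucl, lcl, center = (ucl + lcl) / 2) {
  structure(list(center = center, stat_sd = NA_real_, ucl = ucl, lcl = lcl,
                 a = NA_real_, b = NA_real_),
            class = "control_limits")
}

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}
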