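# Synthetic analyte-result streams.
#
# Routine clinical analytes (hormones, coagulation times) are strictly
# positive and usually right-skewed with a long upper tail. A log-normal
# family parameterized by median and coefficient of variation, plus an
# optional multiplicative upper-tail contamination, reproduces that shape
# well enough to exercise every downstream monitoring stage.

#' Describe a synthetic analyte distribution
#'
#' An `analyte_preset` captures the distributional shape of a patient-result
#' stream: its median and fractional coefficient of variation (CV) on the
#' original measurement scale, plus a `skew_strength` knob that adds sparse
#' multiplicative upper-tail contamination on top of the log-normal core.
#'
#' @param name Label for the preset (used in file names and reports).
#' @param median Target median on the measurement scale; must be positive.
#' @param cv Target fractional coefficient of variation (e.g. `0.03` for 3%);
#'   must be positive.
#' @param skew_strength Nonnegative real controlling upper-tail heaviness.
#'   `0` gives a pure log-normal draw; each unit adds roughly 1% of
#'   observations inflated by a factor drawn from `Uniform(2, 4)`.
#' @param n Number of results to generate; at least 1.
#' @param seed Integer seed making the draw reproducible.
#'
#' @return An object of class `analyte_preset`.
#' @seealso [generate_analyte()], [tsh_like()], [pt_like()]
#' @export
analyte_preset <- function(name, median, cv, skew_strength = 0, n = 7000L,
                           seed = 1L) {
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single string", call. = FALSE)
  }
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median) ||
      median <= 0) {
    stop("`median` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0) {
    stop("`cv` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(skew_strength) || length(skew_strength) != 1L ||
      !is.finite(skew_strength) || skew_strength < 0) {
    stop("`skew_strength` must be a single nonnegative number", call. = FALSE)
  }
  n <- suppressWarnings(as.integer(n))
  if (is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name, median = median, cv = cv,
         skew_strength = skew_strength, n = n, seed = as.integer(seed)),
    class = "analyte_preset"
  )
}

#' @export
print.analyte_preset <- function(x, ...) {
  cat(sprintf(
    "<analyte_preset '%s'> median %g, CV %g, skew_strength %g, n = %d, seed %d\n",
    x$name, x$median, x$cv, x$skew_strength, x$n, x$seed
  ))
  invisible(x)
}

#' High-CV, heavily skewed analyte preset (TSH-like)
#'
#' Thyroid-stimulating hormone is the archetype of a difficult PBRTQC
#' analyte: wide between-patient variation (CV near 0.8) and a long upper
#' tail, so a Box-Cox exponent well below 1 is required to symmetrize it.
#'
#' @param n,seed Record count and seed, passed to [analyte_preset()].
#' @return An `analyte_preset`.
#' @export
tsh_like <- function(n = 7000L, seed = 1L) {
  analyte_preset("tsh_like", median = 1.8, cv = 0.8, skew_strength = 1,
                 n = n, seed = seed)
}

#' Low-CV, mildly skewed analyte preset (PT-like)
#'
#' Prothrombin time behaves almost normally on the measurement scale:
#' a tight population distribution (CV near 0.03) around a median of about
#' 12 seconds with only mild skew.
#'
#' @param n,seed Record count and seed, passed to [analyte_preset()].
#' @return An `analyte_preset`.
#' @export
pt_like <- function(n = 7000L, seed = 1L) {
  analyte_preset("pt_like", median = 12, cv = 0.03, skew_strength = 0,
                 n = n, seed = seed)
}

#' Generate a synthetic patient-result stream
#'
#' Draws `preset$n` strictly positive results from a log-normal distribution
#' with the requested median and CV (meanlog = log(median),
#' sdlog = sqrt(log(1 + cv^2))). When `skew_strength > 0`, a sparse fraction
#' `min(0.01 * skew_strength, 0.1)` of observations is multiplied by a factor
#' drawn from Uniform(2, 4), thickening the upper tail without moving the
#' median. Timestamps are strictly increasing integers; the workflow uses
#' them only for ordering.
#'
#' @param preset An [analyte_preset()].
#' @return An [analyte_series()] with `preset$n` values in chronological
#'   order. The same preset (same seed) always yields the same series.
#' @examples
#' s <- generate_analyte(pt_like(n = 500, seed = 42))
#' summary(s$values)
#' @export
generate_analyte <- function(preset) {
  if (!inherits(preset, "analyte_preset")) {
    stop("`preset` must be an analyte_preset", call. = FALSE)
  }
  sdlog <- sqrt(log(1 + preset$cv^2))
  meanlog <- log(preset$median)
  values <- withr::with_seed(preset$seed, {
    x <- stats::rlnorm(preset$n, meanlog = meanlog, sdlog = sdlog)
    p_cont <- min(0.01 * preset$skew_strength, 0.1)
    if (p_cont > 0) {
      hit <- stats::runif(preset$n) < p_cont
      x[hit] <- x[hit] * stats::runif(sum(hit), 2, 4)
    }
    x
  })
  analyte_series(values, timestamps = seq_along(values),
                 instrument = preset$name)
}

#' Write a patient-result stream as delimited text
#'
#' Emits the two-column layout (`result`, `timestamp`) consumed by
#' [read_analyte()], as comma-separated UTF-8 text with a header row.
#'
#' @param series An [analyte_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analyte <- function(series, path) {
  series <- as_analyte_series(series)
  ts <- if (is.null(series$timestamps)) seq_along(series$values) else
    series$timestamps
  utils::write.csv(
    data.frame(result = series$values, timestamp = ts),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
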