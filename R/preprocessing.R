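# Cleaning, transformation and truncation: the "transform-truncate" stages.
#
# All quantiles in the package use linear interpolation between order
# statistics (stats::quantile type 7), stated here once and used everywhere.

#' An ordered stream of patient results
#'
#' Thin container for a chronologically ordered numeric result stream with
#' optional timestamps and an instrument label. Most functions in the
#' package also accept a bare numeric vector.
#'
#' @param values Numeric vector of finite results in chronological order.
#' @param timestamps Optional vector, nondecreasing, same length as `values`.
#' @param instrument Optional single label.
#' @return An object of class `analyte_series`.
#' @export
analyte_series <- function(values, timestamps = NULL, instrument = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("`values` must be nonempty", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  if (!is.null(timestamps)) {
    if (length(timestamps) != length(values)) {
      stop("`timestamps` must match `values` in length", call. = FALSE)
    }
    if (is.unsorted(timestamps)) {
      stop("`timestamps` must be nondecreasing (chronological order)",
           call. = FALSE)
    }
  }
  structure(list(values = values, timestamps = timestamps,
                 instrument = instrument),
            class = "analyte_series")
}

#' @export
print.analyte_series <- function(x, ...) {
  cat(sprintf("<analyte_series> %d results%s\n", length(x$values),
              if (is.null(x$instrument)) "" else
                paste0(" [", x$instrument, "]")))
  cat(sprintf("  median %.4g, CV %.3g\n", stats::median(x$values),
              stats::sd(x$values) / mean(x$values)))
  invisible(x)
}

#' Coerce to an analyte series
#' @param x A numeric vector or `analyte_series`.
#' @return An `analyte_series`.
#' @export
as_analyte_series <- function(x) {
  if (inherits(x, "analyte_series")) return(x)
  analyte_series(x)
}

# Numeric payload of a series-or-vector argument.
series_values <- function(x) {
  if (inherits(x, "analyte_series")) x$values else as.numeric(x)
}

#' Parse raw result tokens into a numeric stream
#'
#' Laboratory exports mix plain numbers with censored results such as
#' `"<0.01"` or `">100"`. Leading comparator symbols (`<`, `>`, `<=`, `>=`,
#' and their Unicode forms) are stripped so the reported bound is kept as
#' the value; tokens that still fail to parse are dropped and counted in a
#' message. Order is preserved.
#'
#' @param raw Character or numeric vector of result tokens.
#' @param timestamps Optional timestamps, subset alongside the kept tokens.
#' @return An [analyte_series()] of the parseable values.
#' @export
clean_numeric <- function(raw, timestamps = NULL) {
  if (length(raw) == 0L) {
    stop("`raw` must be nonempty", call. = FALSE)
  }
  tok <- trimws(as.character(raw))
  tok <- sub("^[<>=≤≥]+\\s*", "", tok)
  parsed <- suppressWarnings(as.numeric(tok))
  keep <- !is.na(parsed) & is.finite(parsed)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("clean_numeric: dropped %d unparseable token(s)", dropped))
  }
  if (!any(keep)) {
    stop("no parseable numeric results in input", call. = FALSE)
  }
  analyte_series(parsed[keep],
                 timestamps = if (!is.null(timestamps)) timestamps[keep])
}

#' Read a patient-result stream from delimited text
#'
#' Reads a comma- or tab-separated file with a header row and returns the
#' cleaned stream. Column names are configurable so arbitrary LIS exports
#' map onto the (result, timestamp, instrument) layout.
#'
#' @param path File path.
#' @param result_col,timestamp_col,instrument_col Column names; the
#'   timestamp and instrument columns are optional and ignored when absent.
#' @param sep Field separator (`","` default).
#' @return An [analyte_series()].
#' @export
read_analyte <- function(path, result_col = "result",
                         timestamp_col = "timestamp",
                         instrument_col = "instrument", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!result_col %in% names(df)) {
    stop(sprintf("column '%s' not found in %s", result_col, path),
         call. = FALSE)
  }
  ts <- if (timestamp_col %in% names(df)) df[[timestamp_col]]
  instr <- if (instrument_col %in% names(df))
    as.character(df[[instrument_col]][1L])
  s <- clean_numeric(df[[result_col]], timestamps = ts)
  s$instrument <- instr
  s
}

#' Estimate a Box-Cox transform specification
#'
#' Fits the Box-Cox exponent by maximizing the profile log-likelihood of the
#' (shifted) values over `lambda` in `range`. When the series contains
#' non-positive values a small offset, `1e-6 * median(|x|) - min(x)`, shifts
#' everything strictly positive first. When the estimated exponent is
#' closer to zero than `threshold`, the spec records a plain log transform
#' instead (`used_log = TRUE`), the standard continuity choice at
#' `lambda = 0`.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param threshold Positive cut below which `|lambda|` falls back to log.
#'   The default 0.05 is a conventional "close to zero" cut.
#' @param range Search interval for `lambda`.
#' @return A `transform_spec`: list with `lambda`, `offset`,
#'   `log_fallback_threshold`, `used_log`.
#' @examples
#' x <- generate_analyte(tsh_like(n = 2000, seed = 7))
#' estimate_transform(x)
#' @export
estimate_transform <- function(series, threshold = 0.05,
                               range = c(-2, 2)) {
  x <- series_values(series)
  if (length(x) < 2L) {
    stop("need at least two values to estimate a transform", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("constant series: Box-Cox lambda is undefined", call. = FALSE)
  }
  offset <- 0
  if (min(x) <= 0) {
    offset <- 1e-6 * stats::median(abs(x)) - min(x)
    if (offset <= 0) offset <- 1e-6  # all-zero pathological input
  }
  y <- x + offset
  n <- length(y)
  sum_log <- sum(log(y))
  # Profile log-likelihood of the one-parameter Box-Cox model.
  loglik <- function(lambda) {
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * sum_log
  }
  opt <- stats::optimize(loglik, interval = range, maximum = TRUE)
  lambda <- opt$maximum
  used_log <- abs(lambda) < threshold
  structure(
    list(lambda = lambda, offset = offset,
         log_fallback_threshold = threshold, used_log = used_log),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> lambda = %.4g%s, offset = %g\n", x$lambda,
              if (x$used_log) " (log fallback)" else "", x$offset))
  invisible(x)
}

#' Apply a Box-Cox or log transform
#'
#' Elementwise `((x + offset)^lambda - 1) / lambda`, or
#' `log(x + offset)` when the spec fell back to log. Strictly monotone
#' increasing in `x` for any spec, so ordering on the transformed scale
#' mirrors the measurement scale.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param spec A `transform_spec` from [estimate_transform()], or a list
#'   with `lambda`, `offset`, `used_log`.
#' @return Numeric vector on the transformed scale, same length and order.
#' @export
apply_transform <- function(series, spec) {
  x <- series_values(series)
  y <- x + spec$offset
  if (any(y <= 0)) {
    stop("non-positive value after offset: spec does not match data",
         call. = FALSE)
  }
  if (isTRUE(spec$used_log)) log(y) else (y^spec$lambda - 1) / spec$lambda
}

#' Invert a Box-Cox or log transform
#'
#' @param z Numeric vector on the transformed scale.
#' @param spec The `transform_spec` used forward.
#' @return Values on the original measurement scale.
#' @export
invert_transform <- function(z, spec) {
  y <- if (isTRUE(spec$used_log)) exp(z) else
    (z * spec$lambda + 1)^(1 / spec$lambda)
  y - spec$offset
}

#' Fit Winsorizing truncation bounds from training data
#'
#' Bounds are the empirical `factor` and `1 - factor` quantiles (type-7,
#' linear interpolation) of the training values on the transformed scale.
#' They are meant to be frozen here and reused on validation and monitored
#' streams, keeping monitoring causal. `factor = 0` yields infinite bounds
#' (a no-op rule).
#'
#' @param train Numeric vector or [analyte_series()] of training values on
#'   the scale monitoring runs on.
#' @param factor Fraction clamped per tail, in `[0, 0.5)`.
#' @return A `truncation_rule`: list with `factor`, `lower_bound`,
#'   `upper_bound`.
#' @export
fit_truncation <- function(train, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 0 || factor >= 0.5) {
    stop("`factor` must lie in [0, 0.5)", call. = FALSE)
  }
  x <- series_values(train)
  if (length(x) == 0L) stop("`train` must be nonempty", call. = FALSE)
  if (factor == 0) {
    bounds <- c(-Inf, Inf)
  } else {
    bounds <- stats::quantile(x, probs = c(factor, 1 - factor),
                              names = FALSE, type = 7)
  }
  structure(list(factor = factor, lower_bound = bounds[1L],
                 upper_bound = bounds[2L]),
            class = "truncation_rule")
}

#' @export
print.truncation_rule <- function(x, ...) {
  cat(sprintf("<truncation_rule> factor %g per tail, bounds [%g, %g]\n",
              x$factor, x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Winsorize a stream against fixed bounds
#'
#' Values below the rule's lower bound are replaced by the lower bound,
#' values above the upper bound by the upper bound; everything else is
#' untouched. Idempotent and length-preserving.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param rule A `truncation_rule` from [fit_truncation()].
#' @return Numeric vector, clamped.
#' @export
winsorize <- function(series, rule) {
  if (rule$lower_bound > rule$upper_bound) {
    stop("truncation rule has unordered bounds", call. = FALSE)
  }
  pmin(pmax(series_values(series), rule$lower_bound), rule$upper_bound)
}

#' Trim extreme values by the interquartile-range rule
#'
#' Drops observations outside `[Q1 - k*IQR, Q3 + k*IQR]`. This is a
#' visualization helper only — for inspecting distributional shape in
#' histograms — and never feeds modelling; the monitoring pipeline uses the
#' full transformed stream with Winsorization instead.
#'
#' @param x Numeric vector.
#' @param k IQR multiplier (default 1.5).
#' @return The subset of `x` within the fences.
#' @export
iqr_trim <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  x[x >= q[1L] - k * diff(q) & x <= q[2L] + k * diff(q)]
}
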