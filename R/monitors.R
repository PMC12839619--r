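# Monitoring statistics, control limits and the consecutive-alarm rule.

#' Describe one monitor parameter combination
#'
#' Bundles everything that defines a single PBRTQC chart: the algorithm, its
#' algorithm-specific parameter (window width for MA/MQ, quantile level for
#' MQ, smoothing constant for EWMA), the Winsorizing truncation factor, the
#' upper (`a`) and lower (`b`) control-limit multipliers, and the number of
#' consecutive outside-limits points `k` required to raise an alarm.
#'
#' @param algorithm `"MA"`, `"MQ"` or `"EWMA"`.
#' @param window Positive integer trailing-window width (MA and MQ).
#' @param quantile Quantile level in `(0, 1)` (MQ only).
#' @param smoothing EWMA smoothing constant in `(0, 1]`: the weight on the
#'   newest observation (distinct from the Box-Cox exponent).
#' @param truncation_factor Winsorizing fraction per tail, in `[0, 0.5)`.
#' @param a,b Positive multipliers of the statistic's training SD for the
#'   upper and lower control limits.
#' @param k Required run length of consecutive outside-limits points.
#' @return A `monitor_config`.
#' @export
monitor_config <- function(algorithm = c("MA", "MQ", "EWMA"), window = NULL,
                           quantile = NULL, smoothing = NULL,
                           truncation_factor = 0, a = 3, b = 3, k = 5L) {
  algorithm <- match.arg(algorithm)
  if (algorithm %in% c("MA", "MQ")) {
    if (is.null(window) || window < 1L) {
      stop(sprintf("%s requires a positive `window`", algorithm),
           call. = FALSE)
    }
    window <- as.integer(window)
  } else if (!is.null(window)) {
    stop("`window` applies to MA/MQ only", call. = FALSE)
  }
  if (algorithm == "MQ") {
    if (is.null(quantile) || quantile <= 0 || quantile >= 1) {
      stop("MQ requires `quantile` in (0, 1)", call. = FALSE)
    }
  } else if (!is.null(quantile)) {
    stop("`quantile` applies to MQ only", call. = FALSE)
  }
  if (algorithm == "EWMA") {
    if (is.null(smoothing) || smoothing <= 0 || smoothing > 1) {
      stop("EWMA requires `smoothing` in (0, 1]", call. = FALSE)
    }
  } else if (!is.null(smoothing)) {
    stop("`smoothing` applies to EWMA only", call. = FALSE)
  }
  if (truncation_factor < 0 || truncation_factor >= 0.5) {
    stop("`truncation_factor` must lie in [0, 0.5)", call. = FALSE)
  }
  if (a <= 0 || b <= 0) stop("`a` and `b` must be positive", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  structure(
    list(algorithm = algorithm, window = window, quantile = quantile,
         smoothing = smoothing, truncation_factor = truncation_factor,
         a = a, b = b, k = k),
    class = "monitor_config"
  )
}

#' @export
print.monitor_config <- function(x, ...) {
  par <- switch(x$algorithm,
    MA = sprintf("window %d", x$window),
    MQ = sprintf("window %d, quantile %g", x$window, x$quantile),
    EWMA = sprintf("smoothing %g", x$smoothing)
  )
  cat(sprintf("<monitor_config> %s (%s), truncation %g, a = %g, b = %g, k = %d\n",
              x$algorithm, par, x$truncation_factor, x$a, x$b, x$k))
  invisible(x)
}

#' Moving average statistic
#'
#' Arithmetic mean over the trailing window. The first `window - 1`
#' positions are the warm-up and are returned as `NA`; they never alarm and
#' are excluded from limit fitting and metric denominators.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param window Positive integer, at most the series length.
#' @return Numeric vector of the same length.
#' @export
compute_ma <- function(series, window) {
  x <- series_values(series)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window > length(x)) {
    stop("`window` exceeds the series length", call. = FALSE)
  }
  zoo::rollmean(x, k = window, fill = NA, align = "right")
}

#' Moving quantile statistic
#'
#' Empirical quantile (type-7, linear interpolation — the package-wide
#' quantile definition) over the trailing window, `NA` during warm-up.
#'
#' @inheritParams compute_ma
#' @param quantile Quantile level in `(0, 1)`; `0.5` gives a moving median.
#' @return Numeric vector of the same length.
#' @export
compute_mq <- function(series, window, quantile = 0.5) {
  x <- series_values(series)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window > length(x)) {
    stop("`window` exceeds the series length", call. = FALSE)
  }
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must lie in (0, 1)", call. = FALSE)
  }
  zoo::rollapply(x, width = window, align = "right", fill = NA,
                 FUN = stats::quantile, probs = quantile, names = FALSE,
                 type = 7)
}

#' Exponentially weighted moving average statistic
#'
#' Recursion `s_t = smoothing * x_t + (1 - smoothing) * s_{t-1}` with
#' `s_1 = x_1` (causal initialization: no training-mean leakage). Defined at
#' every position, so EWMA has no warm-up.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param smoothing Weight on the newest observation, in `(0, 1]`;
#'   `1` reproduces the raw series.
#' @return Numeric vector of the same length.
#' @export
compute_ewma <- function(series, smoothing) {
  x <- series_values(series)
  if (smoothing <= 0 || smoothing > 1) {
    stop("`smoothing` must lie in (0, 1]", call. = FALSE)
  }
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  if (smoothing == 1) return(x)
  as.numeric(stats::filter(smoothing * x, filter = 1 - smoothing,
                           method = "recursive", init = x[1L]))
}

# Dispatch a config to its statistic.
compute_statistic <- function(series, config) {
  switch(config$algorithm,
    MA = compute_ma(series, config$window),
    MQ = compute_mq(series, config$window, config$quantile),
    EWMA = compute_ewma(series, config$smoothing)
  )
}

#' Fit control limits from a bias-free training statistic
#'
#' Center and spread are the mean and standard deviation of the monitoring
#' statistic itself, computed on the bias-free training stream after
#' warm-up. The limits are `center + a * sd` above and `center - b * sd`
#' below, so multipliers like 1.64, 1.96 and 3 behave as z-quantile
#' multipliers of the statistic's own empirical distribution. Limits fitted
#' here are frozen and applied unchanged to validation streams.
#'
#' @param train_statistic Statistic values on the bias-free training stream
#'   (warm-up `NA`s are ignored).
#' @param a,b Positive upper and lower multipliers.
#' @return A `control_limits`: list with `center`, `stat_sd`, `ucl`, `lcl`.
#' @export
fit_limits <- function(train_statistic, a, b) {
  v <- train_statistic[!is.na(train_statistic)]
  if (length(v) < 2L) {
    stop("need at least two defined statistic values", call. = FALSE)
  }
  if (a <= 0 || b <= 0) stop("`a` and `b` must be positive", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) {
    stop("degenerate training statistic: zero standard deviation",
         call. = FALSE)
  }
  m <- mean(v)
  structure(list(center = m, stat_sd = s, ucl = m + a * s, lcl = m - b * s,
                 a = a, b = b),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("<control_limits> center %.4g, sd %.4g, UCL %.4g, LCL %.4g\n",
              x$center, x$stat_sd, x$ucl, x$lcl))
  invisible(x)
}

#' Raise alarms under the consecutive-point rule
#'
#' A point is outside when the statistic strictly exceeds the UCL or falls
#' strictly below the LCL (warm-up `NA` positions are never outside); a run
#' of consecutive outside points may mix sides. Maximal runs of length at
#' least `k` become alarm runs; every observation of a qualifying run is
#' marked alarmed, and the run is retrospectively attributed to its first
#' point — so a run beginning at the start of an error segment yields a
#' detection delay of zero.
#'
#' @param statistic Monitoring statistic vector (may contain warm-up `NA`s).
#' @param limits A [fit_limits()] result.
#' @param k Required consecutive outside points, `>= 1`.
#' @return An `alarm_trace`: list with `statistic`, `outside` (logical),
#'   `alarmed` (logical), `alarm_runs` (data frame with `start`, `length`),
#'   `limits`, `k`.
#' @export
detect_alarms <- function(statistic, limits, k) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  outside <- !is.na(statistic) &
    (statistic > limits$ucl | statistic < limits$lcl)
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  runs <- data.frame(start = starts[keep], length = r$lengths[keep])
  alarmed <- logical(length(outside))
  for (i in seq_len(nrow(runs))) {
    alarmed[seq.int(runs$start[i], length.out = runs$length[i])] <- TRUE
  }
  structure(
    list(statistic = statistic, outside = outside, alarmed = alarmed,
         alarm_runs = runs, limits = limits, k = k),
    class = "alarm_trace"
  )
}

#' @export
print.alarm_trace <- function(x, ...) {
  cat(sprintf("<alarm_trace> %d observations, %d alarm run(s), %d alarmed (k = %d)\n",
              length(x$statistic), nrow(x$alarm_runs), sum(x$alarmed), x$k))
  invisible(x)
}

#' Run one monitor over a transformed stream
#'
#' Convenience wrapper chaining the truncate-monitor-alarm stages:
#' Winsorize with `rule`, compute the config's statistic, and flag alarms
#' against `limits`. When `limits` is `NULL` they are fitted from this
#' stream's own statistic (training use).
#'
#' @param transformed Numeric vector on the monitoring (transformed) scale.
#' @param config A [monitor_config()].
#' @param rule A [fit_truncation()] rule (fit on training data).
#' @param limits Frozen [fit_limits()] result, or `NULL` to fit here.
#' @return An `alarm_trace`.
#' @export
monitor_stream <- function(transformed, config, rule, limits = NULL) {
  w <- winsorize(transformed, rule)
  stat <- compute_statistic(w, config)
  if (is.null(limits)) limits <- fit_limits(stat, config$a, config$b)
  detect_alarms(stat, limits, config$k)
}

#' Tabulate a control chart
#'
#' Per-observation table suitable for delimited-text export: raw and
#' transformed values, the monitoring statistic, limits, outside/alarmed
#' flags, and — when a scenario is given — the error flag and segment id.
#'
#' @param trace An [detect_alarms()] result.
#' @param raw Optional raw-scale values.
#' @param transformed Optional transformed-scale values.
#' @param scenario Optional `error_scenario` supplying labels.
#' @return A data frame, one row per observation.
#' @export
chart_table <- function(trace, raw = NULL, transformed = NULL,
                        scenario = NULL) {
  n <- length(trace$statistic)
  out <- data.frame(index = seq_len(n),
                    statistic = trace$statistic,
                    ucl = trace$limits$ucl, lcl = trace$limits$lcl,
                    outside = trace$outside, alarmed = trace$alarmed)
  if (!is.null(raw)) out$raw <- raw
  if (!is.null(transformed)) out$transformed <- transformed
  if (!is.null(scenario)) {
    out$error_flag <- scenario$error_flag
    out$segment_id <- scenario$segment_id
  }
  out
}

#' Plot a control chart
#'
#' ggplot2 rendering of the monitoring statistic with the control limits;
#' unbiased observations in blue, biased ones in red when a scenario is
#' supplied.
#'
#' @inheritParams chart_table
#' @return A ggplot object.
#' @export
plot_control_chart <- function(trace, scenario = NULL) {
  df <- data.frame(index = seq_along(trace$statistic),
                   statistic = trace$statistic)
  df$biased <- if (is.null(scenario)) FALSE else scenario$error_flag
  ggplot2::ggplot(df, ggplot2::aes(x = index, y = statistic,
                                   colour = biased)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = trace$limits$ucl, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = trace$limits$lcl, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 name = "biased") +
    ggplot2::labs(x = "patient result (chronological)",
                  y = "monitoring statistic")
}
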