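# Simulated systematic error: stepwise bias and baseline-drift-plateau
# ramps injected into bias-free streams, with per-observation labels.
#
# Bias is always applied on the ORIGINAL measurement scale, before any
# transformation: a "+30% bias" is only physically meaningful as a
# proportional shift of the reported result, not of its Box-Cox image.

#' Place error segments along a stream
#'
#' Draws `n_segments` non-overlapping contiguous segments inside a stream of
#' `n_total` observations. Segment lengths are uniform integers from
#' `length_range` and the gaps between consecutive segments uniform integers
#' from `gap_range`. The gap before the first segment is drawn from
#' `lead_range` (errors may begin soon after monitoring starts), and the
#' trailing gap absorbs whatever remains, which is why realized trailing
#' gaps are typically large. A draw whose total exceeds `n_total` is
#' rejected and redrawn; geometry that cannot fit even at the minimum is an
#' error.
#'
#' @param n_total Stream length the layout must fit inside.
#' @param n_segments Number of error segments (default 5).
#' @param length_range Integer interval for segment lengths
#'   (default `c(100, 300)` consecutive results).
#' @param gap_range Integer interval for the gaps between segments
#'   (default `c(250, 500)` error-free results).
#' @param lead_range Integer interval for the gap before the first segment
#'   (default `c(0, 100)`).
#' @param seed Integer seed; the layout is reproducible bit-for-bit.
#' @return A `segment_layout`: list with `n_total`, `starts` (1-based first
#'   index of each segment) and `lengths`.
#' @examples
#' generate_segment_layout(3500, seed = 1)
#' @export
generate_segment_layout <- function(n_total, n_segments = 5L,
                                    length_range = c(100L, 300L),
                                    gap_range = c(250L, 500L),
                                    lead_range = c(0L, 100L),
                                    seed = 1L) {
  n_total <- as.integer(n_total)
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("`n_segments` must be >= 1", call. = FALSE)
  chk_range <- function(r, nm, lo = 0L) {
    if (length(r) != 2L || any(r < lo) || r[1L] > r[2L]) {
      stop(sprintf("`%s` must be an ordered pair of integers >= %d", nm, lo),
           call. = FALSE)
    }
    as.integer(r)
  }
  length_range <- chk_range(length_range, "length_range", 1L)
  gap_range <- chk_range(gap_range, "gap_range")
  lead_range <- chk_range(lead_range, "lead_range")
  min_need <- lead_range[1L] + n_segments * length_range[1L] +
    (n_segments - 1L) * gap_range[1L]
  if (min_need > n_total) {
    stop(sprintf(
      "infeasible layout: %d segments of >= %d with gaps >= %d need %d > n_total = %d",
      n_segments, length_range[1L], gap_range[1L], min_need, n_total
    ), call. = FALSE)
  }
  runif_int <- function(k, r) {
    if (r[1L] == r[2L]) rep(r[1L], k) else
      r[1L] + floor(stats::runif(k) * (r[2L] - r[1L] + 1L))
  }
  withr::with_seed(seed, {
    for (try in seq_len(1000L)) {
      lead <- runif_int(1L, lead_range)
      lengths <- runif_int(n_segments, length_range)
      gaps <- if (n_segments > 1L) runif_int(n_segments - 1L, gap_range)
      else integer(0)
      if (lead + sum(lengths) + sum(gaps) <= n_total) {
        starts <- lead + 1L +
          cumsum(c(0L, lengths[-n_segments] + gaps))
        return(structure(
          list(n_total = n_total, starts = as.integer(starts),
               lengths = as.integer(lengths)),
          class = "segment_layout"
        ))
      }
    }
  })
  stop("could not draw a feasible layout in 1000 attempts; loosen the ranges",
       call. = FALSE)
}

#' @export
print.segment_layout <- function(x, ...) {
  cat(sprintf("<segment_layout> %d segments in %d observations\n",
              length(x$starts), x$n_total))
  cat(sprintf("  starts:  %s\n", paste(x$starts, collapse = ", ")))
  cat(sprintf("  lengths: %s\n", paste(x$lengths, collapse = ", ")))
  invisible(x)
}

# Per-observation segment id (0 = unbiased) for a layout.
layout_segment_id <- function(layout) {
  id <- integer(layout$n_total)
  for (j in seq_along(layout$starts)) {
    id[seq.int(layout$starts[j], length.out = layout$lengths[j])] <- j
  }
  id
}

new_error_scenario <- function(name, magnitude, direction, values,
                               segment_id, layout) {
  structure(
    list(name = name, magnitude = magnitude, direction = direction,
         values = values, error_flag = segment_id > 0L,
         segment_id = segment_id, layout = layout),
    class = "error_scenario"
  )
}

#' @export
print.error_scenario <- function(x, ...) {
  cat(sprintf("<error_scenario '%s'> %d observations, %d biased in %d segments\n",
              x$name, length(x$values), sum(x$error_flag),
              length(x$layout$starts)))
  invisible(x)
}

#' Inject a stepwise proportional bias
#'
#' Multiplies every on-segment value by `1 + direction * magnitude` on the
#' original measurement scale and leaves all off-segment values untouched.
#' Each observation gets an error flag and a segment id (0 off-segment).
#'
#' @param series Numeric vector or [analyte_series()], bias-free.
#' @param layout A [generate_segment_layout()] result with
#'   `n_total == length(series)`.
#' @param magnitude Fractional bias in `(0, 1)`, e.g. `0.3` for 30%.
#' @param direction `+1` (proportional increase) or `-1` (decrease).
#' @return An `error_scenario`.
#' @export
inject_step_bias <- function(series, layout, magnitude, direction = 1L) {
  x <- series_values(series)
  if (length(x) != layout$n_total) {
    stop("series length does not match layout$n_total", call. = FALSE)
  }
  if (!is.numeric(magnitude) || magnitude <= 0 || magnitude >= 1) {
    stop("`magnitude` must lie in (0, 1)", call. = FALSE)
  }
  if (!direction %in% c(-1, 1)) {
    stop("`direction` must be +1 or -1", call. = FALSE)
  }
  id <- layout_segment_id(layout)
  values <- x
  on <- id > 0L
  values[on] <- x[on] * (1 + direction * magnitude)
  name <- sprintf("error_%s_%d",
                  if (direction > 0) "increase" else "decrease",
                  round(100 * magnitude))
  new_error_scenario(name, magnitude, as.integer(direction), values, id,
                     layout)
}

#' Specify a baseline-drift-plateau error pattern
#'
#' Models progressive instrument deterioration or reagent degradation: the
#' proportional bias starts at `baseline_bias`, rises linearly over
#' `ramp_length` observations to `max_bias`, and then stays at `max_bias`
#' for the rest of the segment.
#'
#' @param baseline_bias Small nonnegative fractional bias at segment onset.
#' @param max_bias Plateau fractional bias, `>= baseline_bias`.
#' @param ramp_length Observations over which the bias climbs; must not
#'   exceed any segment length it is applied to.
#' @return A `drift_spec` list.
#' @export
drift_spec <- function(baseline_bias = 0.01, max_bias = 0.5,
                       ramp_length = 50L) {
  if (baseline_bias < 0) stop("`baseline_bias` must be >= 0", call. = FALSE)
  if (max_bias < baseline_bias) {
    stop("`max_bias` must be >= `baseline_bias`", call. = FALSE)
  }
  ramp_length <- as.integer(ramp_length)
  if (ramp_length < 1L) stop("`ramp_length` must be >= 1", call. = FALSE)
  structure(list(baseline_bias = baseline_bias, max_bias = max_bias,
                 ramp_length = ramp_length),
            class = "drift_spec")
}

#' Inject a gradually drifting bias
#'
#' Within each segment, the per-observation bias fraction at (1-based)
#' segment position `j` is
#' `baseline + (max - baseline) * min((j - 1) / ramp_length, 1)`:
#' the first on-segment observation carries the baseline bias, the ramp
#' completes after `ramp_length` further observations, and the plateau holds
#' `max_bias` to the segment end. Values become
#' `x * (1 + direction * bias)`. With `baseline_bias == max_bias` this
#' reduces exactly to [inject_step_bias()] at that magnitude.
#'
#' @inheritParams inject_step_bias
#' @param spec A [drift_spec()].
#' @return An `error_scenario` whose `magnitude` is the plateau bias.
#' @export
inject_drift_bias <- function(series, layout, spec, direction = 1L) {
  x <- series_values(series)
  if (length(x) != layout$n_total) {
    stop("series length does not match layout$n_total", call. = FALSE)
  }
  if (!direction %in% c(-1, 1)) {
    stop("`direction` must be +1 or -1", call. = FALSE)
  }
  if (any(spec$ramp_length > layout$lengths)) {
    stop("`ramp_length` exceeds a segment length", call. = FALSE)
  }
  id <- layout_segment_id(layout)
  values <- x
  for (j in seq_along(layout$starts)) {
    idx <- seq.int(layout$starts[j], length.out = layout$lengths[j])
    pos <- seq_along(idx)
    bias <- spec$baseline_bias + (spec$max_bias - spec$baseline_bias) *
      pmin((pos - 1) / spec$ramp_length, 1)
    values[idx] <- x[idx] * (1 + direction * bias)
  }
  name <- sprintf("drift_%s_%d",
                  if (direction > 0) "increase" else "decrease",
                  round(100 * spec$max_bias))
  new_error_scenario(name, spec$max_bias, as.integer(direction), values, id,
                     layout)
}

#' Build the standard ten-scenario error suite
#'
#' One scenario per (magnitude, direction) pair; with the default five
#' magnitudes that is ten scenarios per stream. The positive and negative
#' scenarios of a magnitude share the same layout, so increase/decrease
#' pairs differ only in bias direction. Layouts are drawn one per magnitude
#' from `seed` unless supplied.
#'
#' @param series Numeric vector or [analyte_series()], bias-free.
#' @param magnitudes Fractional bias magnitudes
#'   (default `c(0.1, 0.3, 0.5, 0.7, 0.9)`).
#' @param layouts Optional named list of layouts, one per magnitude (names
#'   `"0.1"` etc. as produced by `as.character(magnitudes)`). Generated when
#'   `NULL`.
#' @param seed Seed for layout generation (one derived seed per magnitude).
#' @param drift Optional [drift_spec()]; when given, drift scenarios with
#'   `max_bias = magnitude` replace the stepwise ones.
#' @param ... Passed to [generate_segment_layout()] (layout ranges).
#' @return List of `error_scenario` objects, decreases first then increases,
#'   in magnitude order within each direction.
#' @export
build_scenario_suite <- function(series, magnitudes = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 layouts = NULL, seed = 1L, drift = NULL,
                                 ...) {
  if (length(magnitudes) == 0L) return(list())
  x <- series_values(series)
  if (is.null(layouts)) {
    layouts <- lapply(seq_along(magnitudes), function(i) {
      generate_segment_layout(length(x), seed = seed + i - 1L, ...)
    })
    names(layouts) <- as.character(magnitudes)
  }
  suite <- list()
  for (direction in c(-1L, 1L)) {
    for (m in magnitudes) {
      layout <- layouts[[as.character(m)]]
      if (is.null(layout)) {
        stop(sprintf("no layout supplied for magnitude %s", m), call. = FALSE)
      }
      sc <- if (is.null(drift)) {
        inject_step_bias(x, layout, m, direction)
      } else {
        inject_drift_bias(x, layout,
                          drift_spec(min(drift$baseline_bias, m), m,
                                     drift$ramp_length),
                          direction)
      }
      suite[[sc$name]] <- sc
    }
  }
  suite
}

#' Summarize the segment geometry of a scenario suite
#'
#' One row per scenario: the gap before the first segment, then alternating
#' segment lengths and inter-segment gaps, and finally the trailing gap.
#' Every row partitions the stream, so the row total equals the stream
#' length.
#'
#' @param suite List of `error_scenario` objects (or a single one).
#' @return A data frame with columns `scenario`, `gap_1`, `segment_1`,
#'   `gap_1_2`, ..., `segment_k`, `gap_k_`, `total`.
#' @export
summarize_layouts <- function(suite) {
  if (inherits(suite, "error_scenario")) suite <- list(suite)
  if (length(suite) == 0L) stop("`suite` must be nonempty", call. = FALSE)
  if (is.null(names(suite))) {
    names(suite) <- vapply(suite, `[[`, character(1), "name")
  }
  rows <- lapply(suite, function(sc) {
    lay <- sc$layout
    k <- length(lay$starts)
    ends <- lay$starts + lay$lengths - 1L
    lead <- lay$starts[1L] - 1L
    inner <- if (k > 1L) lay$starts[-1L] - ends[-k] - 1L else integer(0)
    trail <- lay$n_total - ends[k]
    vals <- c(lead, as.vector(rbind(lay$lengths,
                                    c(inner, trail))))
    nm <- c("gap_1",
            as.vector(rbind(paste0("segment_", seq_len(k)),
                            c(if (k > 1L) paste0("gap_", seq_len(k - 1L), "_",
                                                 2:k),
                              paste0("gap_", k, "_")))))
    out <- as.data.frame(as.list(stats::setNames(vals, nm)))
    out$total <- sum(vals)
    out
  })
  cbind(scenario = names(suite), do.call(rbind, rows), row.names = NULL)
}

#' Export a scenario as delimited text
#'
#' One row per observation with columns `index`, `value`, `error_flag`,
#' `segment_id`, matching the layout used by control-chart exports.
#'
#' @param scenario An `error_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  utils::write.csv(
    data.frame(index = seq_along(scenario$values),
               value = scenario$values,
               error_flag = as.integer(scenario$error_flag),
               segment_id = scenario$segment_id),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
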