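# Scoring an alarm trace against a labelled error scenario.
#
# Warm-up positions (statistic NA) are excluded from every numerator and
# denominator: the monitor is simply not running there.

#' Weights of the composite ME_Score
#'
#' The composite objective is
#' `ME_Score = w_sens * Sensitivity + w_fpr * (1 - FPR)
#'   - w_delay * Sigmoid(MNPed)`
#' with `Sigmoid(m) = 1 / (1 + exp(-slope * (m - center)))`. The defaults
#' put almost all weight on keeping the false-positive rate low — a
#' false-alarm tolerance on the order of 1e-3 — with small symmetric
#' rewards for sensitivity and speed; the logistic delay penalty crosses
#' 0.5 at 101 patients.
#'
#' @param w_sens,w_fpr,w_delay Weights on sensitivity, `1 - FPR` and the
#'   sigmoid delay penalty.
#' @param sigmoid_slope,sigmoid_center Logistic slope and center (patients).
#' @return An `me_weights` list.
#' @export
me_weights <- function(w_sens = 0.0005, w_fpr = 0.999, w_delay = 0.0005,
                       sigmoid_slope = 0.05, sigmoid_center = 101) {
  structure(list(w_sens = w_sens, w_fpr = w_fpr, w_delay = w_delay,
                 sigmoid_slope = sigmoid_slope,
                 sigmoid_center = sigmoid_center),
            class = "me_weights")
}

#' Per-segment detection status and delay
#'
#' A segment counts as detected when at least one alarm-run *start* falls
#' inside it; the run-start rule is applied literally, so a run that starts
#' in a gap and spills into a segment is not a detection. The delay is the
#' earliest in-segment run start minus the segment start, in observations —
#' zero when the run begins exactly at error onset.
#'
#' @param trace An [detect_alarms()] result.
#' @param scenario The `error_scenario` the trace was computed on.
#' @return Data frame with one row per segment: `segment`, `start`,
#'   `length`, `detected`, `delay` (`NA` when undetected).
#' @export
segment_detections <- function(trace, scenario) {
  if (length(trace$statistic) != length(scenario$values)) {
    stop("trace and scenario cover different stream lengths", call. = FALSE)
  }
  lay <- scenario$layout
  run_starts <- trace$alarm_runs$start
  out <- data.frame(segment = seq_along(lay$starts), start = lay$starts,
                    length = lay$lengths, detected = FALSE,
                    delay = NA_real_)
  for (j in seq_along(lay$starts)) {
    lo <- lay$starts[j]
    hi <- lo + lay$lengths[j] - 1L
    hits <- run_starts[run_starts >= lo & run_starts <= hi]
    if (length(hits) > 0L) {
      out$detected[j] <- TRUE
      out$delay[j] <- min(hits) - lo
    }
  }
  out
}

#' Sensitivity of a monitor on a scenario
#'
#' Observation mode (the default): the fraction of biased observations that
#' are alarmed. Segment mode: the fraction of error segments detected per
#' [segment_detections()]. Warm-up positions are excluded.
#'
#' @inheritParams segment_detections
#' @param mode `"observation"` or `"segment"`.
#' @return A proportion in `[0, 1]`.
#' @export
sensitivity <- function(trace, scenario,
                        mode = c("observation", "segment")) {
  mode <- match.arg(mode)
  if (mode == "segment") {
    det <- segment_detections(trace, scenario)
    return(mean(det$detected))
  }
  defined <- !is.na(trace$statistic)
  biased <- scenario$error_flag & defined
  if (!any(biased)) {
    stop("scenario has no biased observations after warm-up", call. = FALSE)
  }
  sum(trace$alarmed & biased) / sum(biased)
}

#' False-positive rate of a monitor on a scenario
#'
#' The fraction of unbiased (off-segment) observations that are alarmed,
#' excluding warm-up positions.
#'
#' @inheritParams segment_detections
#' @return A proportion in `[0, 1]`.
#' @export
false_positive_rate <- function(trace, scenario) {
  defined <- !is.na(trace$statistic)
  unbiased <- !scenario$error_flag & defined
  if (!any(unbiased)) {
    stop("scenario has no unbiased observations after warm-up",
         call. = FALSE)
  }
  sum(trace$alarmed & unbiased) / sum(unbiased)
}

#' Median number of patients before error detection (MNPed)
#'
#' Median of the per-segment detection delays. The default policy takes
#' the median over detected segments only and returns `NA` when nothing was
#' detected; `"penalize_missed"` substitutes the full segment length for
#' each missed segment first.
#'
#' @param delays Numeric delays per segment (`NA` for undetected), e.g. the
#'   `delay` column of [segment_detections()].
#' @param policy `"detected_only"` or `"penalize_missed"`.
#' @param segment_lengths Required for `"penalize_missed"`.
#' @return Median delay in patients, or `NA_real_` when undefined.
#' @export
mnped <- function(delays, policy = c("detected_only", "penalize_missed"),
                  segment_lengths = NULL) {
  policy <- match.arg(policy)
  if (length(delays) == 0L) stop("need at least one segment", call. = FALSE)
  if (policy == "penalize_missed") {
    if (is.null(segment_lengths) ||
        length(segment_lengths) != length(delays)) {
      stop("`segment_lengths` must accompany policy 'penalize_missed'",
           call. = FALSE)
    }
    delays[is.na(delays)] <- segment_lengths[is.na(delays)]
  } else {
    delays <- delays[!is.na(delays)]
    if (length(delays) == 0L) return(NA_real_)
  }
  stats::median(delays)
}

#' Logistic delay penalty on MNPed
#'
#' `1 / (1 + exp(-slope * (mnped - center)))`: near 0 for immediate
#' detection, 0.5 at the center (101 patients by default), approaching 1
#' for very slow detection.
#'
#' @param mnped Median detection delay in patients; finite.
#' @param weights An [me_weights()] supplying slope and center.
#' @return A value in `(0, 1)`.
#' @export
sigmoid_penalty <- function(mnped, weights = me_weights()) {
  if (anyNA(mnped)) {
    stop("`mnped` must be defined; the caller decides the undefined policy",
         call. = FALSE)
  }
  1 / (1 + exp(-weights$sigmoid_slope * (mnped - weights$sigmoid_center)))
}

#' Composite ME_Score
#'
#' `w_sens * sensitivity + w_fpr * (1 - fpr) - w_delay * Sigmoid(mnped)`.
#' An undefined MNPed (nothing detected) contributes the maximal penalty
#' `Sigmoid = 1`: a monitor that never detects must not score better than
#' one that detects slowly.
#'
#' @param sensitivity,fpr Proportions in `[0, 1]`.
#' @param mnped Median delay in patients, or `NA` when nothing was detected.
#' @param weights An [me_weights()].
#' @return The composite score (at most `w_sens + w_fpr - 0`).
#' @export
me_score <- function(sensitivity, fpr, mnped, weights = me_weights()) {
  if (sensitivity < 0 || sensitivity > 1 || fpr < 0 || fpr > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  sig <- if (is.na(mnped)) 1 else sigmoid_penalty(mnped, weights)
  weights$w_sens * sensitivity + weights$w_fpr * (1 - fpr) -
    weights$w_delay * sig
}

#' Score one scenario
#'
#' Computes the full metric row for a single (trace, scenario) pair:
#' observation-level sensitivity, FPR, per-segment detections, MNPed and
#' the scenario-level ME_Score.
#'
#' @inheritParams segment_detections
#' @param weights An [me_weights()].
#' @param sensitivity_mode Passed to [sensitivity()].
#' @return A `scenario_metrics` list with fields `scenario`, `sensitivity`,
#'   `fpr`, `mnped`, `me_score`, `detected_segments`, `total_segments`,
#'   `delays`.
#' @export
score_scenario <- function(trace, scenario, weights = me_weights(),
                           sensitivity_mode = "observation") {
  det <- segment_detections(trace, scenario)
  sens <- sensitivity(trace, scenario, mode = sensitivity_mode)
  fpr <- false_positive_rate(trace, scenario)
  m <- mnped(det$delay)
  structure(
    list(scenario = scenario$name, sensitivity = sens, fpr = fpr,
         mnped = m, me_score = me_score(sens, fpr, m, weights),
         detected_segments = sum(det$detected),
         total_segments = nrow(det), delays = det$delay),
    class = "scenario_metrics"
  )
}

#' Aggregate scenario metrics into a performance summary
#'
#' Overall sensitivity and FPR are unweighted means across scenarios; the
#' overall MNPed is the median of the per-segment delays pooled across all
#' scenarios (detected segments only). The aggregate ME_Score is computed
#' from that aggregated triple ("aggregate-then-score"); the mean of the
#' per-scenario ME_Scores ("score-then-average") is also reported as
#' `me_score_mean` since the two orderings differ in general.
#'
#' @param scores List of [score_scenario()] results.
#' @param weights An [me_weights()].
#' @return A `performance_summary`: list with `sensitivity`, `fpr`,
#'   `mnped`, `me_score`, `me_score_mean`, `n_scenarios`, and `per_scenario`
#'   (a data frame).
#' @export
aggregate_metrics <- function(scores, weights = me_weights()) {
  if (length(scores) == 0L) stop("need at least one scenario", call. = FALSE)
  sens <- mean(vapply(scores, `[[`, numeric(1), "sensitivity"))
  fpr <- mean(vapply(scores, `[[`, numeric(1), "fpr"))
  pooled <- unlist(lapply(scores, `[[`, "delays"))
  pooled <- pooled[!is.na(pooled)]
  m <- if (length(pooled) == 0L) NA_real_ else stats::median(pooled)
  per <- data.frame(
    scenario = vapply(scores, `[[`, character(1), "scenario"),
    sensitivity = vapply(scores, `[[`, numeric(1), "sensitivity"),
    fpr = vapply(scores, `[[`, numeric(1), "fpr"),
    mnped = vapply(scores, `[[`, numeric(1), "mnped"),
    me_score = vapply(scores, `[[`, numeric(1), "me_score"),
    detected_segments = vapply(scores, `[[`, integer(1),
                               "detected_segments"),
    total_segments = vapply(scores, `[[`, integer(1), "total_segments"),
    row.names = NULL
  )
  structure(
    list(sensitivity = sens, fpr = fpr, mnped = m,
         me_score = me_score(sens, fpr, m, weights),
         me_score_mean = mean(per$me_score),
         n_scenarios = length(scores), per_scenario = per),
    class = "performance_summary"
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance_summary> %d scenario(s)\n  ME_Score %.4f | sensitivity %.4f | FPR %.4f | MNPed %s\n",
    x$n_scenarios, x$me_score, x$sensitivity, x$fpr,
    if (is.na(x$mnped)) "undefined" else format(x$mnped)
  ))
  invisible(x)
}
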