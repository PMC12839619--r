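# Grid search over monitor parameters, two-stage selection, validation.

grid_defaults <- list(
  full = list(
    window = c(3L, 5L, 10L, 20L, 50L),
    quantile = c(0.25, 0.5, 0.75),
    smoothing = seq(0.1, 0.9, by = 0.1),
    truncation_factor = c(0, 0.01, 0.02, 0.05),
    a = c(1.64, 1.96, 2.58, 3),
    b = c(1.64, 1.96, 2.58, 3),
    k = c(1L, 3L, 5L, 10L)
  ),
  reduced = list(
    window = c(3L, 10L),
    quantile = 0.5,
    smoothing = c(0.4, 0.9),
    truncation_factor = c(0, 0.02),
    a = c(1.96, 3),
    b = c(1.96, 3),
    k = 5L
  )
)

#' Build the parameter grid for one algorithm
#'
#' Expands the cartesian product of per-field candidate lists into
#' [monitor_config()] objects. The `"full"` preset covers the search ranges
#' a routine optimization would scan (e.g. the EWMA full grid has
#' 9 x 4 x 4 x 4 x 4 = 2304 combinations); the `"reduced"` preset is a
#' small grid for quick runs and examples. Any field can be overridden.
#'
#' @param algorithm `"MA"`, `"MQ"` or `"EWMA"`.
#' @param overrides Named list replacing any candidate list, e.g.
#'   `list(k = 5L)`.
#' @param preset `"full"` or `"reduced"`.
#' @return List of `monitor_config` objects.
#' @examples
#' length(build_grid("EWMA"))  # 2304
#' @export
build_grid <- function(algorithm = c("MA", "MQ", "EWMA"),
                       overrides = list(), preset = c("full", "reduced")) {
  algorithm <- match.arg(algorithm)
  preset <- match.arg(preset)
  base <- grid_defaults[[preset]]
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown grid field '%s'", nm), call. = FALSE)
    }
    base[[nm]] <- overrides[[nm]]
  }
  fields <- switch(algorithm,
    MA = c("window", "truncation_factor", "a", "b", "k"),
    MQ = c("window", "quantile", "truncation_factor", "a", "b", "k"),
    EWMA = c("smoothing", "truncation_factor", "a", "b", "k")
  )
  for (f in fields) {
    if (length(base[[f]]) == 0L) {
      stop(sprintf("grid field '%s' must be nonempty", f), call. = FALSE)
    }
  }
  combos <- expand.grid(base[fields], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    row <- combos[i, , drop = FALSE]
    monitor_config(
      algorithm = algorithm,
      window = if ("window" %in% fields) row$window,
      quantile = if ("quantile" %in% fields) row$quantile,
      smoothing = if ("smoothing" %in% fields) row$smoothing,
      truncation_factor = row$truncation_factor,
      a = row$a, b = row$b, k = row$k
    )
  })
}

#' Attach transformed values to a scenario suite
#'
#' Transforms each scenario's biased values with the (training-fitted)
#' transform spec, storing them as `$transformed` so grid evaluation does
#' not re-transform per configuration.
#'
#' @param suite List of `error_scenario` objects.
#' @param tspec A [estimate_transform()] spec.
#' @return The suite with `$transformed` added to each scenario.
#' @export
prepare_scenarios <- function(suite, tspec) {
  lapply(suite, function(sc) {
    sc$transformed <- apply_transform(sc$values, tspec)
    sc
  })
}

#' Evaluate one configuration on training scenarios
#'
#' Runs the full truncate-monitor-alarm-score pipeline for a single
#' parameter combination: Winsorizing bounds are fitted from the bias-free
#' training stream at the config's truncation factor, control limits from
#' that stream's own statistic, and each scenario is then monitored and
#' scored with those frozen pieces. Configurations whose training statistic
#' degenerates (zero spread) are returned as failed with a diagnostic, not
#' dropped silently.
#'
#' @param config A [monitor_config()].
#' @param train_transformed Bias-free training stream on the transformed
#'   scale.
#' @param scenarios Suite prepared by [prepare_scenarios()].
#' @param weights An [me_weights()].
#' @param sensitivity_mode Passed to [score_scenario()].
#' @return A `grid_result`: list with `config`, `summary`
#'   (a [aggregate_metrics()] result or `NULL`), `rule`, `limits`,
#'   `failed`, `message`.
#' @export
evaluate_config <- function(config, train_transformed, scenarios,
                            weights = me_weights(),
                            sensitivity_mode = "observation") {
  res <- tryCatch({
    rule <- fit_truncation(train_transformed, config$truncation_factor)
    base_stat <- compute_statistic(winsorize(train_transformed, rule),
                                   config)
    limits <- fit_limits(base_stat, config$a, config$b)
    scores <- lapply(scenarios, function(sc) {
      trace <- monitor_stream(sc$transformed, config, rule, limits)
      score_scenario(trace, sc, weights, sensitivity_mode)
    })
    list(config = config, summary = aggregate_metrics(scores, weights),
         rule = rule, limits = limits, failed = FALSE, message = NA_character_)
  }, error = function(e) {
    list(config = config, summary = NULL, rule = NULL, limits = NULL,
         failed = TRUE, message = conditionMessage(e))
  })
  structure(res, class = "grid_result")
}

#' Evaluate a whole grid
#'
#' Pure map of [evaluate_config()] over the configurations — no shared
#' mutable state, so results are identical regardless of evaluation order.
#' With `workers > 1` the map runs through [parallel::mclapply()].
#'
#' @param configs List of [monitor_config()] objects (see [build_grid()]).
#' @param train_transformed,scenarios,weights,sensitivity_mode As in
#'   [evaluate_config()].
#' @param workers Worker processes (default 1).
#' @return List of `grid_result` objects, in input order.
#' @export
run_grid <- function(configs, train_transformed, scenarios,
                     weights = me_weights(),
                     sensitivity_mode = "observation", workers = 1L) {
  eval_one <- function(cfg) {
    evaluate_config(cfg, train_transformed, scenarios, weights,
                    sensitivity_mode)
  }
  if (workers > 1L) {
    parallel::mclapply(configs, eval_one, mc.cores = workers)
  } else {
    lapply(configs, eval_one)
  }
}

config_row <- function(config) {
  data.frame(
    algorithm = config$algorithm,
    window = if (is.null(config$window)) NA_integer_ else config$window,
    quantile = if (is.null(config$quantile)) NA_real_ else config$quantile,
    smoothing = if (is.null(config$smoothing)) NA_real_ else
      config$smoothing,
    truncation_factor = config$truncation_factor,
    a = config$a, b = config$b, k = config$k
  )
}

#' Tabulate grid results
#'
#' One row per configuration with its parameters, aggregated metrics and
#' ME_Score rank (rank 1 = highest ME_Score; failed configurations rank
#' last and carry `NA` metrics).
#'
#' @param results List of `grid_result` objects from [run_grid()].
#' @return A data frame ordered as evaluated, with a `rank` column.
#' @export
grid_table <- function(results) {
  rows <- lapply(results, function(r) {
    row <- config_row(r$config)
    if (r$failed) {
      row$me_score <- row$sensitivity <- row$fpr <- row$mnped <- NA_real_
    } else {
      row$me_score <- r$summary$me_score
      row$sensitivity <- r$summary$sensitivity
      row$fpr <- r$summary$fpr
      row$mnped <- r$summary$mnped
    }
    row$failed <- r$failed
    row
  })
  df <- do.call(rbind, rows)
  score <- ifelse(df$failed, -Inf, df$me_score)
  df$rank <- rank(-score, ties.method = "first")
  df
}

#' Two-stage selection of the operating configuration
#'
#' Stage 1 ranks all successful configurations by ME_Score and retains the
#' top fraction (`retain`, at least `min_retain` configurations), which by
#' construction always includes the ME_Score maximum. Stage 2 first demands
#' an acceptable MNPed: preference is given to candidates with a defined
#' detection delay in every scenario (both bias directions, all
#' magnitudes), falling back to candidates detecting at least something,
#' and only then to the rest. Without this screen, a monitor that cannot
#' alarm at all — or is blind to one bias direction, e.g. when its
#' truncation bound sits inside one control limit — trivially achieves
#' zero FPR and would win on that account. The survivors are re-ordered by
#' clinical priority — lower FPR first, then higher sensitivity, then
#' smaller MNPed — and the head is returned. Remaining ties break
#' deterministically on the config fields in order (window, quantile,
#' smoothing, truncation factor, a, b, k, ascending).
#'
#' @param results List of `grid_result` objects.
#' @param retain Fraction retained in stage 1 (default 0.05).
#' @param min_retain Minimum number retained (default 20).
#' @return The selected `grid_result`.
#' @export
two_stage_select <- function(results, retain = 0.05, min_retain = 20L) {
  ok <- Filter(function(r) !r$failed, results)
  if (length(ok) == 0L) {
    stop("all configurations failed; nothing to select", call. = FALSE)
  }
  me <- vapply(ok, function(r) r$summary$me_score, numeric(1))
  n_keep <- min(length(ok), max(ceiling(retain * length(ok)),
                                as.integer(min_retain)))
  kept <- ok[order(-me)][seq_len(n_keep)]
  all_scenarios <- Filter(
    function(r) !anyNA(r$summary$per_scenario$mnped), kept)
  if (length(all_scenarios) > 0L) {
    kept <- all_scenarios
  } else {
    detecting <- Filter(function(r) !is.na(r$summary$mnped), kept)
    if (length(detecting) > 0L) kept <- detecting
  }
  key <- function(r) {
    cfg <- r$config
    c(r$summary$fpr,
      -r$summary$sensitivity,
      if (is.na(r$summary$mnped)) Inf else r$summary$mnped,
      if (is.null(cfg$window)) 0 else cfg$window,
      if (is.null(cfg$quantile)) 0 else cfg$quantile,
      if (is.null(cfg$smoothing)) 0 else cfg$smoothing,
      cfg$truncation_factor, cfg$a, cfg$b, cfg$k)
  }
  keys <- t(vapply(kept, key, numeric(10)))
  ord <- do.call(order, as.data.frame(keys))
  kept[[ord[1L]]]
}

#' Validate a selected configuration on independent scenarios
#'
#' Re-runs monitoring and scoring on the validation suite with the
#' training-frozen truncation bounds and control limits — no parameter is
#' re-estimated ("applied without further tuning").
#'
#' @param selected A `grid_result` (carries its frozen `rule` and
#'   `limits`), typically from [two_stage_select()].
#' @param scenarios Validation suite prepared by [prepare_scenarios()].
#' @param weights,sensitivity_mode As in [evaluate_config()].
#' @return A [aggregate_metrics()] performance summary.
#' @export
validate_config <- function(selected, scenarios, weights = me_weights(),
                            sensitivity_mode = "observation") {
  if (length(scenarios) == 0L) {
    stop("validation scenario list is empty", call. = FALSE)
  }
  if (selected$failed || is.null(selected$limits)) {
    stop("`selected` must be a successfully fitted grid_result",
         call. = FALSE)
  }
  scores <- lapply(scenarios, function(sc) {
    trace <- monitor_stream(sc$transformed, selected$config, selected$rule,
                            selected$limits)
    score_scenario(trace, sc, weights, sensitivity_mode)
  })
  aggregate_metrics(scores, weights)
}
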