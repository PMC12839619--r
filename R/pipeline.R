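# End-to-end orchestration: ingest or synthesize, split, inject, optimize,
# validate, export.

#' Split a stream chronologically
#'
#' The first `floor(ratio * n)` records become the training set and the
#' remainder the validation set; no shuffling, so validation is strictly
#' out-of-sample in time.
#'
#' @param series Numeric vector or [analyte_series()].
#' @param ratio Training fraction in `(0, 1)`; default 0.5 (1:1 split).
#' @return List with `training` and `validation` [analyte_series()].
#' @export
chronological_split <- function(series, ratio = 0.5) {
  s <- as_analyte_series(series)
  n <- length(s$values)
  if (n < 2L) stop("need at least two records to split", call. = FALSE)
  n_train <- floor(ratio * n)
  if (n_train < 1L || n_train >= n) {
    stop("`ratio` must leave both halves nonempty", call. = FALSE)
  }
  idx <- seq_len(n_train)
  sub <- function(i) {
    analyte_series(s$values[i],
                   timestamps = if (!is.null(s$timestamps)) s$timestamps[i],
                   instrument = s$instrument)
  }
  list(training = sub(idx), validation = sub(setdiff(seq_len(n), idx)))
}

#' Run the full monitor-development experiment
#'
#' Orchestrates the whole workflow for one analyte stream: take the most
#' recent `n_records` results, split them chronologically, fit the Box-Cox
#' (or log) transform on the training half, draw one error-segment layout
#' per bias magnitude (the same seeds are used for both halves, so equal
#' halves share identical layouts), build the stepwise-bias scenario suites,
#' grid-search each requested algorithm on the training suite, pick an
#' operating configuration by the two-stage rule, and re-score it on the
#' validation suite with training-frozen limits and truncation bounds.
#'
#' A single `seed` drives the named substreams: data synthesis uses the
#' preset's own seed, layout generation uses `seed + 1, seed + 2, ...` (one
#' per magnitude).
#'
#' @param input An [analyte_preset()] (synthesized on the fly), an
#'   [analyte_series()], or a numeric vector in chronological order.
#' @param n_records Keep at most this many most recent records
#'   (default 7000).
#' @param split_ratio Training fraction (default 0.5).
#' @param algorithms Character subset of `c("MA", "MQ", "EWMA")`.
#' @param magnitudes Fractional bias magnitudes
#'   (default `c(0.1, 0.3, 0.5, 0.7, 0.9)`; ten scenarios with both
#'   directions).
#' @param grid_preset `"reduced"` (default, quick) or `"full"`.
#' @param grid_overrides Named list of per-algorithm override lists, e.g.
#'   `list(EWMA = list(smoothing = 0.9))`.
#' @param length_range,gap_range,lead_range Layout geometry, passed to
#'   [generate_segment_layout()].
#' @param weights An [me_weights()].
#' @param transform_threshold Log-fallback cut for [estimate_transform()].
#' @param sensitivity_mode `"observation"` or `"segment"`.
#' @param retain,min_retain Stage-1 retention for [two_stage_select()].
#' @param seed Integer master seed for layout generation.
#' @param workers Grid-evaluation workers (default 1).
#' @return A `pbrtqc_report`: list with `transform`, `layout_summary`,
#'   per-algorithm `results` (each holding `grid`, `selected`, `training`,
#'   `validation`), and the inputs needed to rerun sensitivity analyses.
#' @examples
#' \donttest{
#' rep <- run_experiment(pt_like(n = 2000, seed = 1), n_records = 2000,
#'                       algorithms = "EWMA", seed = 1)
#' rep$results$EWMA$validation
#' }
#' @export
run_experiment <- function(input, n_records = 7000L, split_ratio = 0.5,
                           algorithms = c("MA", "MQ", "EWMA"),
                           magnitudes = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           grid_preset = c("reduced", "full"),
                           grid_overrides = list(),
                           length_range = c(100L, 300L),
                           gap_range = c(250L, 500L),
                           lead_range = c(0L, 100L),
                           weights = me_weights(),
                           transform_threshold = 0.05,
                           sensitivity_mode = "observation",
                           retain = 0.05, min_retain = 20L,
                           seed = 1L, workers = 1L) {
  grid_preset <- match.arg(grid_preset)
  algorithms <- match.arg(algorithms, c("MA", "MQ", "EWMA"),
                          several.ok = TRUE)
  series <- if (inherits(input, "analyte_preset")) generate_analyte(input)
  else as_analyte_series(input)
  n <- length(series$values)
  if (n > n_records) {
    series <- analyte_series(
      utils::tail(series$values, n_records),
      timestamps = if (!is.null(series$timestamps))
        utils::tail(series$timestamps, n_records),
      instrument = series$instrument
    )
  }
  halves <- chronological_split(series, split_ratio)
  tspec <- estimate_transform(halves$training,
                              threshold = transform_threshold)
  train_t <- apply_transform(halves$training, tspec)

  layout_for <- function(n_total) {
    layouts <- lapply(seq_along(magnitudes), function(i) {
      generate_segment_layout(n_total, length_range = length_range,
                              gap_range = gap_range,
                              lead_range = lead_range, seed = seed + i)
    })
    stats::setNames(layouts, as.character(magnitudes))
  }
  train_layouts <- layout_for(length(halves$training$values))
  val_layouts <- layout_for(length(halves$validation$values))

  train_suite <- build_scenario_suite(halves$training, magnitudes,
                                      layouts = train_layouts)
  val_suite <- build_scenario_suite(halves$validation, magnitudes,
                                    layouts = val_layouts)
  train_prep <- prepare_scenarios(train_suite, tspec)
  val_prep <- prepare_scenarios(val_suite, tspec)

  results <- list()
  for (alg in algorithms) {
    configs <- build_grid(alg, overrides = if (alg %in% names(grid_overrides))
      grid_overrides[[alg]] else list(), preset = grid_preset)
    grid_res <- run_grid(configs, train_t, train_prep, weights,
                         sensitivity_mode, workers)
    selected <- two_stage_select(grid_res, retain, min_retain)
    results[[alg]] <- list(
      grid = grid_table(grid_res),
      selected = selected,
      training = selected$summary,
      validation = validate_config(selected, val_prep, weights,
                                   sensitivity_mode)
    )
  }

  structure(
    list(
      instrument = series$instrument,
      n_records = length(series$values),
      split_ratio = split_ratio,
      seed = seed,
      magnitudes = magnitudes,
      transform = tspec,
      layout_summary = summarize_layouts(train_suite),
      layouts = list(training = train_layouts, validation = val_layouts),
      halves = halves,
      suites = list(training = train_prep, validation = val_prep),
      weights = weights,
      sensitivity_mode = sensitivity_mode,
      results = results
    ),
    class = "pbrtqc_report"
  )
}

#' @export
print.pbrtqc_report <- function(x, ...) {
  cat(sprintf("<pbrtqc_report>%s %d records, split %g, seed %d\n",
              if (is.null(x$instrument)) "" else
                paste0(" [", x$instrument, "]"),
              x$n_records, x$split_ratio, x$seed))
  cat(sprintf("  transform: lambda %.3g%s\n", x$transform$lambda,
              if (x$transform$used_log) " (log)" else ""))
  for (alg in names(x$results)) {
    r <- x$results[[alg]]
    cfg <- r$selected$config
    par <- switch(alg,
      MA = sprintf("window %d", cfg$window),
      MQ = sprintf("window %d, q %g", cfg$window, cfg$quantile),
      EWMA = sprintf("smoothing %g", cfg$smoothing))
    cat(sprintf(
      "  %s (%s, trunc %g, a %g, b %g, k %d):\n", alg, par,
      cfg$truncation_factor, cfg$a, cfg$b, cfg$k))
    for (split in c("training", "validation")) {
      s <- r[[split]]
      cat(sprintf(
        "    %-10s ME_Score %.4f | sens %.4f | FPR %.4f | MNPed %s\n",
        split, s$me_score, s$sensitivity, s$fpr,
        if (is.na(s$mnped)) "undefined" else format(s$mnped)))
    }
  }
  invisible(x)
}

#' Drift-pattern sensitivity analysis
#'
#' Re-evaluates a report's selected configurations — unchanged, with their
#' training-frozen limits — on scenario suites where the abrupt stepwise
#' bias is replaced by a baseline-drift-plateau ramp reaching the same
#' maximum bias. The same layouts are reused, so the unbiased stretches are
#' identical between the step and drift runs.
#'
#' @param report A [run_experiment()] result.
#' @param drift A [drift_spec()]; its `max_bias` is overridden per
#'   magnitude, so only `baseline_bias` and `ramp_length` matter here.
#' @return A data frame comparing step vs drift metrics per algorithm, with
#'   the drift performance summaries attached as attribute `"summaries"`.
#' @export
run_drift_sensitivity <- function(report, drift = drift_spec()) {
  if (!inherits(report, "pbrtqc_report")) {
    stop("`report` must come from run_experiment()", call. = FALSE)
  }
  drift_suite <- build_scenario_suite(
    report$halves$validation, report$magnitudes,
    layouts = report$layouts$validation, drift = drift
  )
  drift_prep <- prepare_scenarios(drift_suite, report$transform)
  rows <- list()
  summaries <- list()
  for (alg in names(report$results)) {
    sel <- report$results[[alg]]$selected
    dsum <- validate_config(sel, drift_prep, report$weights,
                            report$sensitivity_mode)
    ssum <- report$results[[alg]]$validation
    summaries[[alg]] <- dsum
    rows[[alg]] <- data.frame(
      algorithm = alg,
      step_sensitivity = ssum$sensitivity, drift_sensitivity = dsum$sensitivity,
      step_fpr = ssum$fpr, drift_fpr = dsum$fpr,
      step_mnped = ssum$mnped, drift_mnped = dsum$mnped,
      step_me_score = ssum$me_score, drift_me_score = dsum$me_score
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "summaries") <- summaries
  out
}

#' Export every report table as delimited text
#'
#' Writes the layout summary, per-algorithm grid tables, selected-config
#' table and per-scenario metric tables as comma-separated UTF-8 files with
#' header rows under `dir`.
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(report$layout_summary, "layout_summary")
  sel_rows <- lapply(names(report$results), function(alg) {
    r <- report$results[[alg]]
    row <- config_row(r$selected$config)
    for (split in c("training", "validation")) {
      s <- r[[split]]
      row[[paste0(split, "_me_score")]] <- s$me_score
      row[[paste0(split, "_sensitivity")]] <- s$sensitivity
      row[[paste0(split, "_fpr")]] <- s$fpr
      row[[paste0(split, "_mnped")]] <- s$mnped
    }
    row
  })
  emit(do.call(rbind, sel_rows), "selected_configs")
  for (alg in names(report$results)) {
    r <- report$results[[alg]]
    emit(r$grid, paste0("grid_", alg))
    emit(r$training$per_scenario, paste0("training_scenarios_", alg))
    emit(r$validation$per_scenario, paste0("validation_scenarios_", alg))
  }
  invisible(paths)
}
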