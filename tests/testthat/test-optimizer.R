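mock_result <- function(fpr, sens, mnped, me, smoothing = 0.5,
                        per_mnped = mnped, failed = FALSE) {
  structure(
    list(config = monitor_config("EWMA", smoothing = smoothing),
         summary = if (failed) NULL else
           list(me_score = me, fpr = fpr, sensitivity = sens, mnped = mnped,
                per_scenario = data.frame(mnped = per_mnped)),
         rule = NULL, limits = NULL, failed = failed,
         message = NA_character_),
    class = "grid_result"
  )
}

test_that("grids expand to the documented cartesian products", {
  expect_length(build_grid("EWMA"), 9 * 4 * 4 * 4 * 4)
  expect_length(build_grid("MA"), 5 * 4 * 4 * 4 * 4)
  expect_length(build_grid("MQ"), 5 * 3 * 4 * 4 * 4 * 4)
  # pinning one field shrinks the product accordingly
  expect_length(build_grid("EWMA", overrides = list(k = 5L)), 2304 / 4)
  # the recurrent MA optimum shape is reachable
  ma <- build_grid("MA")
  expect_true(any(vapply(ma, function(c) c$window == 3 && c$k == 5,
                         logical(1))))
  expect_error(build_grid("EWMA", overrides = list(smoothing = numeric(0))),
               "nonempty")
  expect_error(build_grid("EWMA", overrides = list(bogus = 1)), "unknown")
})

test_that("the reduced grid reaches the wide-limit EWMA operating point", {
  g <- build_grid("EWMA", preset = "reduced")
  expect_true(any(vapply(g, function(c) {
    c$smoothing == 0.9 && c$a == 3 && c$b == 3 &&
      c$truncation_factor == 0 && c$k == 5
  }, logical(1))))
})

test_that("two-stage selection is FPR-first, then sensitivity, then delay", {
  a <- mock_result(0.002, 0.99, 1, me = 0.9990, smoothing = 0.1)
  b <- mock_result(0.001, 0.80, 9, me = 0.9989, smoothing = 0.2)
  expect_identical(two_stage_select(list(a, b)), b)
  c1 <- mock_result(0.001, 0.9, 5, me = 0.999, smoothing = 0.3)
  c2 <- mock_result(0.001, 0.8, 1, me = 0.999, smoothing = 0.4)
  expect_identical(two_stage_select(list(c2, c1)), c1)
  d1 <- mock_result(0.001, 0.9, 5, me = 0.999, smoothing = 0.3)
  d2 <- mock_result(0.001, 0.9, 2, me = 0.999, smoothing = 0.4)
  expect_identical(two_stage_select(list(d1, d2)), d2)
  single <- mock_result(0.01, 0.5, 10, me = 0.99)
  expect_identical(two_stage_select(list(single)), single)
})

test_that("a monitor that never detects cannot win on zero FPR", {
  dead <- mock_result(0, 0, NA, me = 0.9985, smoothing = 0.1,
                      per_mnped = c(NA, NA))
  oneside <- mock_result(0, 0.49, 0, me = 0.9992, smoothing = 0.2,
                         per_mnped = c(0, NA))
  live <- mock_result(0.0005, 0.95, 1, me = 0.9990, smoothing = 0.3,
                      per_mnped = c(1, 1))
  expect_identical(two_stage_select(list(dead, oneside, live)), live)
  # with no fully-detecting candidate, partial detection still beats none
  expect_identical(two_stage_select(list(dead, oneside)), oneside)
})

test_that("stage-1 retention never discards the ME_Score maximum", {
  results <- withr::with_seed(8, lapply(1:100, function(i) {
    mock_result(runif(1, 0, 0.01), runif(1), sample(0:50, 1),
                me = runif(1, 0.99, 0.9995), smoothing = i / 101)
  }))
  me <- vapply(results, function(r) r$summary$me_score, numeric(1))
  best <- results[[which.max(me)]]
  expect_identical(two_stage_select(results, retain = 0.01, min_retain = 1),
                   best)
})

test_that("all-failed grids raise an optimization error", {
  expect_error(two_stage_select(list(mock_result(0, 0, NA, 0,
                                                 failed = TRUE))),
               "all configurations failed")
})

test_that("degenerate statistics are recorded as failed, not dropped", {
  cfg <- monitor_config("EWMA", smoothing = 0.5)
  sc <- prepare_scenarios(
    build_scenario_suite(rep(5, 1500), magnitudes = 0.5, seed = 1,
                         length_range = c(80, 120),
                         gap_range = c(100, 200)),
    list(lambda = 1, offset = 0, used_log = FALSE)
  )
  res <- evaluate_config(cfg, rep(0, 1500), sc)
  expect_true(res$failed)
  expect_match(res$message, "degenerate")
  tab <- grid_table(list(res))
  expect_true(tab$failed)
  expect_true(is.na(tab$me_score))
})

test_that("grid evaluation is deterministic and order-invariant", {
  x <- generate_analyte(pt_like(n = 1600, seed = 21))
  tspec <- estimate_transform(x)
  xt <- apply_transform(x, tspec)
  suite <- prepare_scenarios(
    build_scenario_suite(x, magnitudes = c(0.3, 0.7), seed = 2,
                         length_range = c(60, 120),
                         gap_range = c(150, 250)),
    tspec
  )
  configs <- build_grid("EWMA", preset = "reduced",
                        overrides = list(truncation_factor = 0))
  r1 <- run_grid(configs, xt, suite)
  r2 <- run_grid(configs, xt, suite)
  expect_identical(grid_table(r1), grid_table(r2))
  perm <- withr::with_seed(9, sample(seq_along(configs)))
  r3 <- run_grid(configs[perm], xt, suite)
  t1 <- grid_table(r1)[perm, setdiff(names(grid_table(r1)), "rank")]
  t3 <- grid_table(r3)[, setdiff(names(grid_table(r3)), "rank")]
  expect_equal(t1, t3, ignore_attr = TRUE)
})

test_that("validation reuses frozen limits and rejects empty suites", {
  x <- generate_analyte(pt_like(n = 1600, seed = 22))
  tspec <- estimate_transform(x)
  xt <- apply_transform(x, tspec)
  suite <- prepare_scenarios(
    build_scenario_suite(x, magnitudes = 0.5, seed = 3,
                         length_range = c(60, 120),
                         gap_range = c(150, 250)),
    tspec
  )
  res <- evaluate_config(monitor_config("EWMA", smoothing = 0.9), xt, suite)
  # validating on the training suite itself reproduces the training summary
  v <- validate_config(res, suite)
  expect_equal(v$sensitivity, res$summary$sensitivity)
  expect_equal(v$fpr, res$summary$fpr)
  expect_equal(v$me_score, res$summary$me_score)
  expect_error(validate_config(res, list()), "empty")
})
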