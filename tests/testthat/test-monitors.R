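test_that("moving average matches per-window means", {
  expect_equal(compute_ma(c(1, 2, 3, 4), 3), c(NA, NA, 2, 3))
  expect_equal(compute_ma(c(5, 1, 9), 1), c(5, 1, 9))
  expect_equal(compute_ma(rep(7, 10), 4), c(rep(NA, 3), rep(7, 7)))
  expect_error(compute_ma(1:3, 5), "exceeds")
  expect_error(compute_ma(1:3, 0), ">= 1")
})

test_that("moving quantile matches sort-based oracles", {
  expect_equal(compute_mq(c(1, 100, 2), 3, 0.5), c(NA, NA, 2))
  x <- c(4, 8, 15, 16)
  expect_equal(compute_mq(x, 1, 0.25), x)
  # median of an even window is the mean of the two central order stats
  expect_equal(compute_mq(c(3, 9, 1, 7), 4, 0.5)[4], mean(c(3, 7)))
  expect_error(compute_mq(1:5, 3, 1), "quantile")
})

test_that("rolling statistics agree with brute-force recomputation", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, rnorm(500))
    for (w in c(2, 5, 17)) {
      ma <- compute_ma(x, w)
      mq <- compute_mq(x, w, 0.25)
      for (i in seq(w, length(x), by = 37)) {
        win <- x[(i - w + 1):i]
        expect_lt(abs(ma[i] - mean(win)), 1e-12)
        expect_lt(abs(mq[i] - quantile(win, 0.25, names = FALSE, type = 7)),
                  1e-12)
      }
      expect_true(all(is.na(ma[seq_len(w - 1)])))
    }
  }
})

test_that("EWMA follows its recursion and identity cases", {
  expect_equal(compute_ewma(c(2, 4), 0.5), c(2, 3))
  x <- withr::with_seed(1, rnorm(50))
  expect_equal(compute_ewma(x, 1), x)
  expect_equal(compute_ewma(rep(3, 20), 0.2), rep(3, 20))
  # manual recursion oracle
  s <- numeric(length(x))
  s[1] <- x[1]
  for (i in 2:length(x)) s[i] <- 0.3 * x[i] + 0.7 * s[i - 1]
  expect_equal(compute_ewma(x, 0.3), s, tolerance = 1e-12)
})

test_that("EWMA stays within the observed range for any smoothing", {
  x <- withr::with_seed(2, rnorm(200))
  for (lam in c(0.1, 0.4, 0.9, 1)) {
    e <- compute_ewma(x, lam)
    expect_gte(min(e), min(x))
    expect_lte(max(e), max(x))
  }
})

test_that("limits reproduce two-sided z coverage on a normal statistic", {
  x <- withr::with_seed(10, rnorm(10000))
  lim <- fit_limits(x, 1.96, 1.96)
  frac <- mean(x > lim$ucl | x < lim$lcl)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  expect_equal(lim$ucl - lim$center, lim$center - lim$lcl)
  asym <- fit_limits(x, 1.64, 3)
  expect_equal(asym$ucl, asym$center + 1.64 * asym$stat_sd)
  expect_equal(asym$lcl, asym$center - 3 * asym$stat_sd)
  expect_error(fit_limits(rep(1, 100), 2, 2), "degenerate")
  expect_error(fit_limits(c(1, NA), 2, 2), "at least two")
})

test_that("consecutive-alarm runs are maximal and start-attributed", {
  lim <- fake_limits(1, -1)
  stat <- c(0, 0, 5, 5, 5, 5, 5, 0)
  tr5 <- detect_alarms(stat, lim, 5)
  expect_equal(tr5$alarm_runs, data.frame(start = 3L, length = 5L))
  expect_equal(which(tr5$alarmed), 3:7)
  tr6 <- detect_alarms(stat, lim, 6)
  expect_equal(nrow(tr6$alarm_runs), 0)
  expect_false(any(tr6$alarmed))
  tr1 <- detect_alarms(stat, lim, 1)
  expect_identical(tr1$alarmed, tr1$outside)
})

test_that("warm-up NAs never alarm and runs may mix sides", {
  lim <- fake_limits(1, -1)
  stat <- c(NA, NA, 5, 5, -5, -5, 5, 0)
  tr <- detect_alarms(stat, lim, 5)
  expect_false(any(tr$outside[1:2]))
  expect_equal(tr$alarm_runs, data.frame(start = 3L, length = 5L))
})

test_that("alarm burden is monotone in k and in the multipliers", {
  x <- withr::with_seed(3, rnorm(2000))
  shifted <- x + c(rep(0, 1000), rep(2.5, 500), rep(0, 500))
  stat <- compute_ewma(shifted, 0.6)
  base <- fit_limits(compute_ewma(x, 0.6), 2, 2)
  alarmed_k <- vapply(c(1, 3, 5, 10), function(k)
    sum(detect_alarms(stat, base, k)$alarmed), numeric(1))
  expect_true(all(diff(alarmed_k) <= 0))
  alarmed_ab <- vapply(c(1.64, 1.96, 2.58, 3), function(m)
    sum(detect_alarms(stat, fit_limits(compute_ewma(x, 0.6), m, m),
                      5)$alarmed), numeric(1))
  expect_true(all(diff(alarmed_ab) <= 0))
})

test_that("monitor_stream chains truncate, monitor, and alarm stages", {
  x <- withr::with_seed(4, rnorm(1000))
  rule <- fit_truncation(x, 0.02)
  cfg <- monitor_config("EWMA", smoothing = 0.5, a = 3, b = 3, k = 3)
  tr <- monitor_stream(x, cfg, rule)
  expect_s3_class(tr, "alarm_trace")
  expect_equal(tr$statistic, compute_ewma(winsorize(x, rule), 0.5))
  # frozen limits are used verbatim
  lim <- fake_limits(100, -100)
  tr2 <- monitor_stream(x, cfg, rule, lim)
  expect_false(any(tr2$alarmed))
})

test_that("monitor configs enforce algorithm-specific fields", {
  expect_error(monitor_config("MA"), "window")
  expect_error(monitor_config("MA", window = 3, quantile = 0.5), "MQ only")
  expect_error(monitor_config("MQ", window = 3), "quantile")
  expect_error(monitor_config("EWMA", smoothing = 1.5), "smoothing")
  expect_error(monitor_config("EWMA", smoothing = 0.5, window = 3),
               "MA/MQ only")
  expect_error(monitor_config("EWMA", smoothing = 0.5,
                              truncation_factor = 0.5), "truncation_factor")
  cfg <- monitor_config("MQ", window = 5, quantile = 0.25, k = 3)
  expect_s3_class(cfg, "monitor_config")
  expect_equal(cfg$k, 3L)
})

test_that("chart tables carry labels and the plot builds", {
  x <- rep(c(0, 3), each = 20)
  lay <- fixed_layout(40, starts = 21, lengths = 20)
  sc <- inject_step_bias(rep(10, 40), lay, 0.5, +1)
  tr <- detect_alarms(x, fake_limits(1, -1), 5)
  tab <- chart_table(tr, raw = sc$values, scenario = sc)
  expect_equal(nrow(tab), 40)
  expect_true(all(c("statistic", "ucl", "lcl", "alarmed", "error_flag",
                    "segment_id", "raw") %in% names(tab)))
  p <- plot_control_chart(tr, sc)
  expect_s3_class(p, "ggplot")
})
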