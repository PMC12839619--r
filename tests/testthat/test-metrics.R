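# A hand-checkable stream: 1000 observations, three 100-long error
# segments, alarm runs constructed directly through the statistic.
metric_fixture <- function() {
  lay <- fixed_layout(1000, starts = c(101, 401, 701),
                      lengths = c(100, 100, 100))
  sc <- inject_step_bias(rep(10, 1000), lay, 0.5, +1)
  stat <- numeric(1000)
  stat[101:110] <- 5   # run starting exactly at segment 1 onset (delay 0)
  stat[406:415] <- 5   # run starting 5 into segment 2 (delay 5)
  stat[600:604] <- 5   # false run of exactly k = 5 in a gap
  trace <- detect_alarms(stat, fake_limits(1, -1), 5)
  list(trace = trace, scenario = sc)
}

test_that("segment detections use the run-start rule with index delays", {
  f <- metric_fixture()
  det <- segment_detections(f$trace, f$scenario)
  expect_equal(det$detected, c(TRUE, TRUE, FALSE))
  expect_equal(det$delay, c(0, 5, NA))
  expect_error(segment_detections(f$trace,
                                  inject_step_bias(rep(10, 500),
                                                   fixed_layout(500, 100, 50),
                                                   0.5)),
               "different stream")
})

test_that("a run starting in a gap is not a segment detection", {
  lay <- fixed_layout(300, starts = 101, lengths = 100)
  sc <- inject_step_bias(rep(10, 300), lay, 0.5, +1)
  stat <- numeric(300)
  stat[96:110] <- 5  # starts 5 before the segment, spills inside
  trace <- detect_alarms(stat, fake_limits(1, -1), 5)
  det <- segment_detections(trace, sc)
  expect_false(det$detected[1])
  # but its in-gap points still count toward the false-positive rate
  expect_gt(false_positive_rate(trace, sc), 0)
})

test_that("sensitivity counts observations by default and segments on request", {
  f <- metric_fixture()
  expect_equal(sensitivity(f$trace, f$scenario), 20 / 300)
  expect_equal(sensitivity(f$trace, f$scenario, mode = "segment"), 2 / 3)
  # runs beginning exactly at each segment onset: both modes reach 1
  onset_stat <- ifelse(f$scenario$error_flag, 5, 0)
  onset <- detect_alarms(onset_stat, fake_limits(1, -1), 5)
  expect_equal(sensitivity(onset, f$scenario), 1)
  expect_equal(sensitivity(onset, f$scenario, mode = "segment"), 1)
})

test_that("false-positive rate counts alarmed unbiased observations", {
  f <- metric_fixture()
  expect_equal(false_positive_rate(f$trace, f$scenario), 5 / 700)
  silent <- detect_alarms(rep(0, 1000), fake_limits(1, -1), 5)
  expect_equal(false_positive_rate(silent, f$scenario), 0)
  expect_equal(sensitivity(silent, f$scenario), 0)
})

test_that("warm-up positions are excluded from metric denominators", {
  lay <- fixed_layout(200, starts = 51, lengths = 100)
  sc <- inject_step_bias(rep(10, 200), lay, 0.5, +1)
  stat <- c(rep(NA, 60), rep(5, 140))  # monitor starts mid-segment
  trace <- detect_alarms(stat, fake_limits(1, -1), 5)
  # biased & defined = positions 61..150 -> 90 of them, all alarmed
  expect_equal(sensitivity(trace, sc), 1)
  expect_equal(false_positive_rate(trace, sc), 1)  # 50 of 50 defined unbiased
})

test_that("MNPed is the median delay under both policies", {
  expect_equal(mnped(c(0, 0, 0, 5, 7)), 0)
  expect_equal(mnped(c(5, 7)), 6)
  expect_true(is.na(mnped(c(NA, NA))))
  expect_equal(mnped(c(0, 5, NA), policy = "penalize_missed",
                     segment_lengths = c(100, 100, 100)), 5)
  expect_error(mnped(numeric(0)), "at least one")
  expect_error(mnped(c(1, NA), policy = "penalize_missed"),
               "segment_lengths")
})

test_that("the sigmoid penalty is centered, bounded and monotone", {
  expect_identical(sigmoid_penalty(101), 0.5)
  expect_equal(sigmoid_penalty(5), 0.00816257115316, tolerance = 1e-10)
  expect_lt(sigmoid_penalty(5), sigmoid_penalty(50))
  expect_lt(sigmoid_penalty(50), sigmoid_penalty(101))
  expect_error(sigmoid_penalty(NA), "defined")
})

test_that("the composite score follows its closed form", {
  expect_equal(me_score(0.7677, 0.0016, 5), 0.997781368714,
               tolerance = 1e-10)
  # perfect detection with unbounded delay approaches w_sens + w_fpr - w_delay
  expect_equal(me_score(1, 0, 1e9), 0.999, tolerance = 1e-9)
  # undefined MNPed takes the maximal penalty
  expect_equal(me_score(0, 0, NA), 0.999 - 0.0005)
  expect_error(me_score(1.2, 0, 5), "rates")
})

test_that("the composite score is monotone in each component", {
  base <- me_score(0.5, 0.001, 20)
  expect_gt(me_score(0.6, 0.001, 20), base)
  expect_lt(me_score(0.5, 0.002, 20), base)
  expect_lt(me_score(0.5, 0.001, 40), base)
  # score range under default weights
  expect_lte(me_score(1, 0, 0), 0.9995)
  expect_gte(me_score(0, 1, NA), -0.0005)
})

test_that("scenario scoring assembles the full metric row", {
  f <- metric_fixture()
  s <- score_scenario(f$trace, f$scenario)
  expect_equal(s$sensitivity, 20 / 300)
  expect_equal(s$fpr, 5 / 700)
  expect_equal(s$mnped, 2.5)
  expect_equal(s$detected_segments, 2)
  expect_equal(s$total_segments, 3)
  expect_equal(s$me_score, me_score(20 / 300, 5 / 700, 2.5))
})

test_that("aggregation averages rates and pools delays", {
  f <- metric_fixture()
  s <- score_scenario(f$trace, f$scenario)
  agg1 <- aggregate_metrics(list(s, s))
  expect_equal(agg1$sensitivity, s$sensitivity)
  expect_equal(agg1$fpr, s$fpr)
  expect_equal(agg1$mnped, s$mnped)
  s2 <- s
  s2$sensitivity <- 1
  s2$delays <- c(3, 7, NA)
  agg2 <- aggregate_metrics(list(s, s2))
  expect_equal(agg2$sensitivity, mean(c(20 / 300, 1)))
  expect_equal(agg2$mnped, median(c(0, 5, 3, 7)))
  expect_gte(agg2$sensitivity, min(s$sensitivity, 1))
  expect_lte(agg2$sensitivity, 1)
  expect_equal(agg2$me_score,
               me_score(agg2$sensitivity, agg2$fpr, agg2$mnped))
  expect_equal(agg2$me_score_mean, mean(c(s$me_score, s2$me_score)))
})

test_that("infinitely wide limits yield zero rates and undefined MNPed", {
  x <- withr::with_seed(6, rlnorm(1500, 2, 0.4))
  lay <- generate_segment_layout(1500, n_segments = 3,
                                 length_range = c(80, 120),
                                 gap_range = c(100, 200), seed = 6)
  sc <- inject_step_bias(x, lay, 0.9, +1)
  trace <- detect_alarms(compute_ewma(sc$values, 0.5),
                         fake_limits(Inf, -Inf), 1)
  expect_equal(sensitivity(trace, sc), 0)
  expect_equal(false_positive_rate(trace, sc), 0)
  expect_true(is.na(mnped(segment_detections(trace, sc)$delay)))
})
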