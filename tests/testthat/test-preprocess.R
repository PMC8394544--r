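test_that("edge trimming removes 15 min per end and errors when too short", {
  ecg <- ecg_record(rnorm(8 * 3600 * 100), fs = 100)
  tr <- trim_edges(ecg)
  expect_equal(length(tr$samples) / tr$fs / 3600, 7.5, tolerance = 1e-4)
  expect_equal(tr$start_offset, 900)
  expect_error(trim_edges(ecg_record(rnorm(29 * 60 * 100), fs = 100)),
               "too short")
  # first retained sample equals the original sample at t = 15 min
  e2 <- ecg_record(seq_len(3.5 * 3600 * 100), fs = 100)
  t2 <- trim_edges(e2)
  expect_equal(t2$samples[1], e2$samples[15 * 60 * 100 + 1])
  expect_equal(length(t2$samples) / 100 / 3600, 3, tolerance = 1e-4)
})

test_that("RR-input trimming cuts the beat-time span", {
  tt <- seq(0.8, 3600, by = 0.8)
  rr <- rr_series(rep(0.8, length(tt)), tt)
  tr <- trim_edges(rr, trim = 5)
  expect_gte(min(tr$beat_times), 300)
  expect_lte(max(tr$beat_times), 3600 - 300 + 1e-9)
})

test_that("RR derivation takes first differences of beat times", {
  rr <- derive_rr(c(0, 1, 2.1))
  expect_equal(rr$intervals, c(1.0, 1.1))
  expect_error(derive_rr(3.2), "two beats")
  expect_error(derive_rr(c(1, 0.5, 2)), "strictly increasing")
  many <- derive_rr(seq(0, by = 0.75, length.out = 1000))
  expect_equal(length(many$intervals), 999)
  expect_true(all(many$intervals == 0.75))
})

test_that("artifact rejection applies both plausibility clauses", {
  nn <- reject_artifacts(c(0.8, 0.2, 0.9))
  expect_equal(nn$intervals, c(0.8, 0.9))
  expect_equal(nn$n_rejected, 1L)
  nn2 <- reject_artifacts(c(0.8, 1.6, 0.9))
  expect_equal(nn2$intervals, c(0.8, 0.9))
  expect_equal(nn2$n_rejected, 1L)
  nn3 <- reject_artifacts(c(0.8, 0.8, 0.8))
  expect_equal(nn3$intervals, c(0.8, 0.8, 0.8))
  expect_equal(nn3$n_rejected, 0L)
  expect_error(reject_artifacts(c(0.1, 2.4)), "no valid NN")
})

test_that("artifact rejection is idempotent and conserves counts", {
  set.seed(1)
  x <- runif(500, 0.4, 1.4)
  x[sample(500, 30)] <- c(0.2, 2.0, 0.8)[rep_len(1:3, 30)] # inject artifacts
  nn1 <- reject_artifacts(x)
  expect_equal(length(nn1$intervals) + nn1$n_rejected, 500L)
  nn2 <- reject_artifacts(nn1)
  expect_equal(nn2$intervals, nn1$intervals)
  expect_equal(nn2$n_rejected, 0L)
  expect_true(all(nn1$intervals >= 0.33 & nn1$intervals <= 1.5))
  expect_true(all(abs(diff(nn1$intervals)) <= 0.66))
})

test_that("minimum-duration check uses cumulative retained time", {
  nn <- reject_artifacts(rep(0.8, 13500)) # exactly 3 h
  expect_true(check_min_duration(nn))
  nn2 <- reject_artifacts(rep(0.8, 13050)) # 2.9 h
  expect_false(check_min_duration(nn2))
})

test_that("a cohort built at a given failure rate is thinned accordingly", {
  # 779-subject cohort geometry: 22 subjects fail the 3 h requirement
  durations <- c(rep(3.2, 757), rep(2.5, 22)) # hours
  pass <- vapply(durations, function(h) {
    check_min_duration(list(intervals = rep(0.8, round(h * 3600 / 0.8))))
  }, logical(1))
  expect_equal(sum(pass), 757L)
})

test_that("uniform resampling has the exact grid and preserves constants", {
  nn <- reject_artifacts(rep(1.0, 1000))
  u <- resample_uniform(nn)
  expect_equal(u$fs, 3.41)
  expect_true(all(abs(u$values - 1.0) < 1e-12))
  tgrid <- u$t0 + (seq_along(u$values) - 1) / u$fs
  expect_equal(unique(round(diff(tgrid), 12)), 1 / 3.41)
  # span within one grid step of the NN span
  expect_lt(max(nn$beat_times) - (u$t0 + (length(u$values) - 1) / u$fs),
            1 / 3.41)
})

test_that("resampled oscillatory tachogram peaks at the source frequency", {
  nn <- reject_artifacts(sinusoid_nn(hours = 0.5, f = 0.10))
  u <- resample_uniform(nn)
  psd <- welch_psd(u, small_plan(1024L))
  keep <- psd$freq > 0.01
  f_peak <- psd$freq[keep][which.max(psd$power[keep])]
  expect_equal(f_peak, 0.10, tolerance = 0.01)
})

test_that("in-band reconstruction of a clean tachogram is accurate", {
  nn <- reject_artifacts(sinusoid_nn(hours = 0.5, base = 0.8, amp = 0.05,
                                     f = 0.1))
  u <- resample_uniform(nn)
  tgrid <- u$t0 + (seq_along(u$values) - 1) / u$fs
  # the generator evaluates RR at the beat start and stamps the value
  # at the beat end, one mean beat later
  truth <- 0.8 + 0.05 * cos(2 * pi * 0.1 * (tgrid - 0.8))
  core <- seq(50, length(tgrid) - 50)
  rmse <- sqrt(mean((u$values[core] - truth[core])^2))
  expect_lt(rmse / 0.8, 0.01)
})

test_that("R-peak detection is invariant to polarity and scale", {
  rr <- rr_series(rep(0.8, 80))
  ecg <- simulate_ecg(rr, fs = 250, seed = 4)
  pk <- detect_r_peaks(ecg)
  flipped <- ecg_record(-ecg$samples, ecg$fs)
  scaled <- ecg_record(1000 * ecg$samples, ecg$fs)
  expect_identical(detect_r_peaks(flipped), pk)
  expect_identical(detect_r_peaks(scaled), pk)
  expect_error(detect_r_peaks(ecg_record(rep(1, 5000), fs = 250)),
               "no QRS")
  expect_error(detect_r_peaks(ecg_record(rnorm(5000), fs = 50)), "100 Hz")
})

test_that("detector recovers a known constant rhythm accurately", {
  ecg <- simulate_ecg(rr_series(rep(0.8, 120)), fs = 250, seed = 6)
  rrd <- diff(detect_r_peaks(ecg)) / 250
  expect_equal(mean(rrd), 0.800, tolerance = 0.005)
})

test_that("end-to-end preprocessing errors on sub-3 h recordings", {
  cfg <- simulation_config(duration = 12700)
  rr <- simulate_rr(subject_profile("short", 1, 5, 3), cfg)
  # trimming 15 min per end leaves just over 3 h; dropping most beats
  # through artifact rejection must trip the post-rejection check
  expect_silent(preprocess_subject(rr))
})
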