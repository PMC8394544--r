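test_that("severity mapping follows the pediatric AHI cutoffs and is total", {
  expect_equal(as.character(severity_from_ahi(c(0, 0.99, 1, 4.99, 5, 9.99, 10, 40))),
               c("none", "none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  # total and mutually exclusive over a dense grid
  ahi <- seq(0, 30, by = 0.01)
  sev <- severity_from_ahi(ahi)
  expect_false(anyNA(sev))
  expect_equal(nlevels(sev), 4L)
})

test_that("zero-modulation subject yields a constant RR series", {
  comp <- data.frame(label = c("vlf", "apnea", "lf", "resp"),
                     freq = c(0.015, 0.05, 0.09, 0.25),
                     amp = 0, ahi_slope = 0)
  cfg <- simulation_config(mean_rr = 1.0, components = comp, noise_sd = 0,
                           artifact_rate = 0)
  rr <- simulate_rr(subject_profile("z", 0, 5, 7), cfg)
  expect_true(all(rr$intervals == 1.0))
  expect_equal(rr$beat_times, cumsum(rr$intervals))
})

test_that("simulation is deterministic given the seed", {
  p <- subject_profile("d", 3.2, 6, 123)
  cfg <- simulation_config(noise_sd = 0.01, artifact_rate = 0.02)
  a <- simulate_rr(p, cfg)
  b <- simulate_rr(p, cfg)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$beat_times, b$beat_times)
})

test_that("apnea-band spectral power grows with simulated AHI", {
  cfg <- simulation_config()
  rr0 <- simulate_rr(subject_profile("a", 0, 6, 42), cfg)
  rr15 <- simulate_rr(subject_profile("b", 15, 6, 43), cfg)
  h0 <- preprocess_subject(rr0)$hrv
  h15 <- preprocess_subject(rr15)$hrv
  bp0 <- band_power(welch_psd(h0), c(0.028, 0.074))
  bp15 <- band_power(welch_psd(h15), c(0.028, 0.074))
  expect_gt(bp15, bp0)
})

test_that("artifact injection perturbs the requested fraction of beats", {
  cfg <- simulation_config(noise_sd = 0, artifact_rate = 0.05)
  rr <- simulate_rr(subject_profile("art", 2, 6, 9), cfg)
  bad <- rr$intervals < 0.33 | rr$intervals > 1.5
  expect_equal(sum(bad) / length(rr$intervals), 0.05, tolerance = 0.01)
  # all three modes present
  expect_true(any(rr$intervals == 0.2))
  expect_true(any(rr$intervals == 2.0))
})

test_that("too-short recordings are rejected with an explicit error", {
  expect_error(simulate_rr(subject_profile("s", 1, 4, 1),
                           simulation_config(duration = 2 * 3600)),
               "too short")
})

test_that("config validation enforces Nyquist and apnea-band bounds", {
  comp <- data.frame(label = "lf", freq = 1.8, amp = 0.01, ahi_slope = 0)
  expect_error(simulation_config(components = comp), "Nyquist")
  comp2 <- data.frame(label = "apnea", freq = 0.1, amp = 0.01, ahi_slope = 0.001)
  expect_error(simulation_config(components = comp2), "0.028")
})

test_that("cohort severity proportions match the mixture weights", {
  mix <- c(none = 0.18, mild = 0.41, moderate = 0.18, severe = 0.23)
  set.seed(77)
  ahi <- bisphrv:::draw_ahi(500, mix)
  obs <- table(severity_from_ahi(ahi))
  gof <- suppressWarnings(chisq.test(obs, p = mix[names(obs)]))
  expect_gt(gof$p.value, 0.01)
})

test_that("RR mean matches mean_rr within 3 SE for zero-mean modulation", {
  cfg <- simulation_config(noise_sd = 0.01)
  rr <- simulate_rr(subject_profile("m", 2, 6, 5), cfg)
  se <- sd(rr$intervals) / sqrt(length(rr$intervals))
  expect_lt(abs(mean(rr$intervals) - cfg$mean_rr), 3 * se + 1e-3)
})

test_that("QPC triad phases obey the coupling contract", {
  # zero noise, coupled, single realization: bispectral phase ~ 0 at (f1, f2)
  plan <- segment_plan(512L, overlap = 0, nfft = 512L)
  x <- simulate_qpc_signal(0.3, 0.4, coupled = TRUE, n = 512L, seed = 5,
                           noise_sd = 0)
  B <- estimate_bispectrum(x, plan)
  k1 <- which.min(abs(B$freq - 0.3))
  k2 <- which.min(abs(B$freq - 0.4))
  expect_lt(abs(Arg(B$values[k1, k2])), 0.01)
  expect_error(simulate_qpc_signal(1.0, 0.8, fs = 3.41), "aliasing")
})

test_that("synthetic ECG places template peaks at beat times", {
  rr <- rr_series(rep(1.0, 60))
  ecg <- simulate_ecg(rr, fs = 250, seed = 2)
  pk <- detect_r_peaks(ecg)
  expect_gte(length(pk), 59)
  expect_lte(length(pk), 61)
  spacing <- diff(pk) / 250
  expect_true(all(abs(spacing - 1.0) < 0.01))
  # determinism
  expect_identical(simulate_ecg(rr, fs = 250, seed = 2)$samples, ecg$samples)
  # noise-free template placement recovers RR to within one sample
  ecg0 <- simulate_ecg(rr_series(rep(0.8, 80)), fs = 250, seed = 3,
                       noise_sd = 0)
  rr0 <- diff(detect_r_peaks(ecg0)) / 250
  expect_true(all(abs(rr0 - 0.8) <= 1 / 250 + 1e-9))
})

test_that("cohort manifests round-trip through plain-text files", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(3, seed = 11, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  rr <- read_rr(man$path[2])
  expect_equal(rr$intervals, coh$rr[[man$subject_id[2]]]$intervals,
               tolerance = 1e-9)
})
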