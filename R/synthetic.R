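# Synthetic ECG/RR cohort generator. The generator is a test fixture
# emulating the statistical structure the analysis assumes (band-limited
# oscillations, an apnea-band component growing with AHI, a respiratory
# component, optional quadratic phase coupling, noise and artifacts);
# it is not a physiological model.

#' Map AHI to the pediatric OSA severity group
#'
#' Pediatric cutoffs: no-OSA `AHI < 1`, mild `1 <= AHI < 5`, moderate
#' `5 <= AHI < 10`, severe `AHI >= 10` events/hour.
#'
#' @param ahi Apnea-Hypopnea Index, events/hour, `>= 0`.
#' @return Ordered factor with levels `none < mild < moderate < severe`.
#' @export
severity_from_ahi <- function(ahi) {
  stopifnot(all(ahi >= 0, na.rm = TRUE))
  cut(ahi, breaks = c(-Inf, 1, 5, 10, Inf), right = FALSE,
      labels = c("none", "mild", "moderate", "severe"),
      ordered_result = TRUE)
}

#' Subject profile for simulation
#'
#' @param subject_id Identifier string.
#' @param ahi Apnea-Hypopnea Index, events/hour, `>= 0`.
#' @param age Age in years, in `[0, 13]`.
#' @param seed Integer RNG seed for this subject.
#' @return An object of class `subject_profile` (severity derived from
#'   `ahi`).
#' @export
subject_profile <- function(subject_id, ahi, age, seed) {
  stopifnot(ahi >= 0, age >= 0, age <= 13)
  structure(list(subject_id = as.character(subject_id), ahi = ahi,
                 age = age,
                 severity = as.character(severity_from_ahi(ahi)),
                 seed = as.integer(seed)),
            class = "subject_profile")
}

default_components <- function(respiratory_freq = 0.25) {
  data.frame(
    label = c("vlf", "apnea", "lf", "resp"),
    freq = c(0.015, 0.05, 0.09, respiratory_freq),
    amp = c(0.015, 0.004, 0.015, 0.020),
    ahi_slope = c(0, 0.0018, 0, 0)
  )
}

#' Simulation configuration
#'
#' Describes the RR tachogram model
#' `RR(t) = mean_rr + sum_i a_i(AHI) cos(2 pi f_i t + phi_i) + eps`,
#' with `a_i(AHI) = amp_i + slope_i * AHI`, sampled at beat times by
#' integrate-and-fire on the instantaneous rate. The default component
#' set places band-limited oscillations in VLF (0.015 Hz), LF
#' (0.09 Hz) and the respiratory band (`respiratory_freq`), plus an
#' apnea-cycle component at 0.05 Hz - inside the 0.028-0.074 Hz
#' apnea-related band - whose amplitude grows linearly with AHI.
#'
#' @param duration Recording length in seconds; must leave at least
#'   3 h after trimming 15 min at each end (default 13000 s, about
#'   3.6 h).
#' @param mean_rr Mean RR interval in seconds (default 0.8 s, a
#'   child-typical heart rate of 75 bpm).
#' @param components Data frame with columns `label`, `freq` (Hz),
#'   `amp` (s), `ahi_slope` (s per e/h).
#' @param respiratory_freq Respiratory frequency in Hz, in
#'   `[0.15, 0.40]`; sets the default respiratory component and hence
#'   the adaptive BWRes band.
#' @param qpc_pairs Optional data frame `f1`, `f2`, `amp`, `coupled`
#'   adding cosine triads at `(f1, f2, f1 + f2)` with coupled
#'   (`phi3 = phi1 + phi2`) or independent phases.
#' @param noise_sd SD of additive white noise on each beat, seconds.
#' @param artifact_rate Fraction of beats perturbed into implausible
#'   values (three modes in equal proportion: 0.2 s short beat, 2.0 s
#'   long beat, +0.8 s step jump).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration = 13000, mean_rr = 0.8,
                              components = NULL, respiratory_freq = 0.25,
                              qpc_pairs = NULL, noise_sd = 0.01,
                              artifact_rate = 0) {
  if (is.null(components)) components <- default_components(respiratory_freq)
  stopifnot(respiratory_freq >= 0.15, respiratory_freq <= 0.40,
            noise_sd >= 0, artifact_rate >= 0, artifact_rate <= 1,
            mean_rr > 0)
  if (any(components$freq >= 1.705)) {
    stop("component frequencies must be below the 1.705 Hz Nyquist limit")
  }
  ap <- components$label == "apnea"
  if (any(ap) && any(components$freq[ap] < 0.028 | components$freq[ap] > 0.074)) {
    stop("apnea component frequency must lie in [0.028, 0.074] Hz")
  }
  structure(list(duration = duration, mean_rr = mean_rr,
                 components = components,
                 respiratory_freq = respiratory_freq,
                 qpc_pairs = qpc_pairs, noise_sd = noise_sd,
                 artifact_rate = artifact_rate),
            class = "simulation_config")
}

#' Simulate an overnight RR tachogram
#'
#' Generates beats by integrate-and-fire on the instantaneous RR model
#' of [simulation_config()]: the next beat falls one current-RR after
#' the previous one. A fraction `artifact_rate` of beats is then
#' replaced by implausible values to exercise the rejection rules.
#' Deterministic given `profile$seed`.
#'
#' @param profile A [subject_profile()].
#' @param config A [simulation_config()].
#' @return An `rr_series` with attribute `profile`.
#' @export
simulate_rr <- function(profile, config = simulation_config()) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "simulation_config"))
  if (config$duration - 2 * 15 * 60 < 3 * 3600) {
    stop("duration too short to yield 3 h after trimming 15 min per end")
  }
  set.seed(profile$seed)
  comp <- config$components
  amps <- comp$amp + comp$ahi_slope * profile$ahi
  phases <- runif(nrow(comp), 0, 2 * pi)
  qpc <- config$qpc_pairs
  if (!is.null(qpc) && nrow(qpc)) {
    qf <- qa <- qp <- numeric(0)
    for (i in seq_len(nrow(qpc))) {
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      p3 <- if (isTRUE(qpc$coupled[i])) p1 + p2 else runif(1, 0, 2 * pi)
      qf <- c(qf, qpc$f1[i], qpc$f2[i], qpc$f1[i] + qpc$f2[i])
      qa <- c(qa, rep(qpc$amp[i], 3))
      qp <- c(qp, p1, p2, p3)
    }
    amps <- c(amps, qa)
    phases <- c(phases, qp)
    freqs <- c(comp$freq, qf)
  } else {
    freqs <- comp$freq
  }
  n_max <- ceiling(config$duration / max(0.2, config$mean_rr - sum(abs(amps)) -
                                           4 * config$noise_sd)) + 16L
  tt <- numeric(n_max)
  rr <- numeric(n_max)
  t <- 0
  i <- 0L
  w <- 2 * pi * freqs
  noise <- if (config$noise_sd > 0) rnorm(n_max, 0, config$noise_sd) else numeric(n_max)
  while (t < config$duration && i < n_max) {
    i <- i + 1L
    v <- config$mean_rr + sum(amps * cos(w * t + phases)) + noise[i]
    v <- max(v, 0.2)
    t <- t + v
    tt[i] <- t
    rr[i] <- v
  }
  tt <- tt[seq_len(i)]
  rr <- rr[seq_len(i)]
  if (config$artifact_rate > 0) {
    n_art <- round(config$artifact_rate * i)
    if (n_art > 0) {
      idx <- sample.int(i, n_art)
      mode <- rep_len(1:3, n_art)
      rr[idx[mode == 1]] <- 0.2
      rr[idx[mode == 2]] <- 2.0
      rr[idx[mode == 3]] <- rr[idx[mode == 3]] + 0.8
    }
  }
  out <- rr_series(rr, tt)
  attr(out, "profile") <- profile
  out
}

#' Simulate a quadratically phase-coupled (or uncoupled) triad
#'
#' Three cosines at `f1`, `f2` and `f1 + f2` with random phases plus
#' white noise. When `coupled`, `phi3 = phi1 + phi2` (quadratic phase
#' coupling, a nonlinear interaction producing a bispectral peak at
#' `(f1, f2)`); otherwise `phi3` is drawn independently, so averaging
#' over independent realizations cancels the bispectrum at that bin.
#' With `n_records > 1`, each record is an independent realization
#' (fresh phases and noise); feed the list straight to
#' [estimate_bispectrum()].
#'
#' @param f1,f2 Component frequencies in Hz; `f1 + f2` must be below
#'   `fs / 2`.
#' @param coupled Logical: quadratic phase coupling present?
#' @param n Samples per record.
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @param n_records Number of independent realizations.
#' @param amp Cosine amplitude.
#' @param noise_sd SD of the additive white noise.
#' @return A `uniform_hrv` (single record) or list of `uniform_hrv`.
#' @export
simulate_qpc_signal <- function(f1, f2, coupled = TRUE, n = 1024L, fs = 3.41,
                                seed = 1L, n_records = 1L, amp = 1,
                                noise_sd = 0.1) {
  if (f1 + f2 >= fs / 2) stop("aliasing violation: f1 + f2 must be below fs/2")
  set.seed(as.integer(seed))
  tvec <- (0:(n - 1)) / fs
  one <- function() {
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
    x <- amp * (cos(2 * pi * f1 * tvec + p1) + cos(2 * pi * f2 * tvec + p2) +
                  cos(2 * pi * (f1 + f2) * tvec + p3))
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    uniform_hrv(x, fs = fs)
  }
  if (n_records == 1L) one() else lapply(seq_len(n_records), function(i) one())
}

#' Simulate an ECG waveform from an RR series
#'
#' Places a fixed QRS-like template (a Gaussian-windowed biphasic
#' spike, about 80 ms wide) at the cumulative beat times on a noisy
#' baseline. The template peak coincides with the beat time to within
#' one sample. Intended as a fixture for R-peak detection, not a
#' morphologically realistic ECG (no P/T waves).
#'
#' @param rr An `rr_series`.
#' @param fs Output sampling rate in Hz (`>= 100`).
#' @param seed Integer RNG seed for the baseline noise.
#' @param noise_sd Baseline noise SD (signal units; template peak is 1).
#' @return An `ecg_record`.
#' @export
simulate_ecg <- function(rr, fs = 250, seed = 1L, noise_sd = 0.02) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  set.seed(as.integer(seed))
  beats <- c(rr$beat_times[1] - rr$intervals[1], rr$beat_times)
  beats <- beats - min(beats)
  dur <- max(beats) + 0.5
  n <- ceiling(dur * fs)
  x <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  half <- round(0.04 * fs)
  tt <- (-half:half) / fs
  template <- (1 - (tt / 0.018)^2 * 0.35) * exp(-(tt / 0.018)^2 / 2)
  for (b in beats) {
    c0 <- round(b * fs) + 1L
    lo <- c0 - half
    hi <- c0 + half
    if (lo < 1L || hi > n) next
    x[lo:hi] <- x[lo:hi] + template
  }
  ecg_record(x, fs)
}

# Draw AHI values from a severity-group mixture (uniform within the
# bounded groups; exponential tail with mean 5 e/h above 10 for the
# severe group). Uses the current RNG state.
draw_ahi <- function(n, ahi_mix) {
  grp <- sample(names(ahi_mix), n, replace = TRUE, prob = ahi_mix)
  vapply(grp, function(g) switch(g,
    none = runif(1, 0, 1), mild = runif(1, 1, 5),
    moderate = runif(1, 5, 10), severe = 10 + rexp(1, 1 / 5)),
    numeric(1), USE.NAMES = FALSE)
}

#' Simulate a cohort of subjects
#'
#' Draws AHI from a four-group severity mixture (uniform within group;
#' the severe tail is exponential above 10 e/h), ages uniform in 0-13
#' years, and generates one RR series per subject. Subject seeds are
#' derived from the cohort seed by counter, so every run is
#' reproducible. The default mixture follows a clinically referred
#' population: 18% no-OSA, 41% mild, 18% moderate, 23% severe.
#'
#' @param n Number of subjects.
#' @param ahi_mix Mixture weights, named `none`, `mild`, `moderate`,
#'   `severe` (normalized internally).
#' @param config Base [simulation_config()] shared by subjects;
#'   per-subject respiratory frequency is drawn uniformly in
#'   `[0.18, 0.35]` Hz unless `fixed_resp = TRUE`.
#' @param seed Cohort RNG seed.
#' @param fixed_resp Keep one respiratory frequency for all subjects.
#' @param out_dir Optional directory: writes each RR series as plain
#'   text (seconds, one interval per line) plus a `manifest.csv` with
#'   `subject_id`, `ahi`, `age`, `severity`, `path`.
#' @return A list with `manifest` (data frame) and `rr` (named list of
#'   `rr_series`).
#' @export
simulate_cohort <- function(n, ahi_mix = c(none = 0.18, mild = 0.41,
                                           moderate = 0.18, severe = 0.23),
                            config = simulation_config(), seed = 1L,
                            fixed_resp = FALSE, out_dir = NULL) {
  stopifnot(n >= 1)
  ahi_mix <- ahi_mix / sum(ahi_mix)
  set.seed(as.integer(seed))
  ahi <- draw_ahi(n, ahi_mix)
  age <- runif(n, 0, 13)
  resp <- if (fixed_resp) rep(config$respiratory_freq, n) else runif(n, 0.18, 0.35)
  ids <- sprintf("S%04d", seq_len(n))
  rr <- vector("list", n)
  names(rr) <- ids
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    profiles[[i]] <- subject_profile(ids[i], ahi[i], age[i],
                                     seed = as.integer(seed) + i)
    cfg <- config
    cfg$respiratory_freq <- resp[i]
    cfg$components <- config$components
    cfg$components$freq[cfg$components$label == "resp"] <- resp[i]
    rr[[i]] <- simulate_rr(profiles[[i]], cfg)
  }
  manifest <- data.frame(subject_id = ids, ahi = ahi, age = age,
                         severity = as.character(severity_from_ahi(ahi)),
                         respiratory_freq = resp, row.names = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".rr.txt"))
    for (i in seq_len(n)) {
      writeLines(format(rr[[i]]$intervals, digits = 10), paths[i])
    }
    manifest$path <- paths
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, rr = rr)
}

#' Read an RR series from a plain-text file
#'
#' One interval in seconds per line.
#'
#' @param path File path.
#' @return An `rr_series`.
#' @export
read_rr <- function(path) {
  rr_series(as.numeric(readLines(path)))
}
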