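# ECG / RR pre-processing: edge trimming, R-peak detection, RR
# derivation, artifact rejection and uniform resampling at 3.41 Hz.

#' ECG record container
#'
#' @param samples Numeric voltage series.
#' @param fs Sampling rate in Hz (`> 0`).
#' @param start_offset Time of the first sample in seconds.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, start_offset = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_offset = start_offset),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d samples at %g Hz (%.1f min), offset %.1f s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs / 60,
              x$start_offset))
  invisible(x)
}

#' Raw RR-interval series container
#'
#' `beat_times` are the times at which each interval ends; when only
#' intervals are supplied the times are their cumulative sums.
#'
#' @param intervals RR intervals in seconds.
#' @param beat_times Optional end time of each interval, in seconds.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, beat_times = NULL) {
  intervals <- as.numeric(intervals)
  stopifnot(length(intervals) >= 1)
  if (is.null(beat_times)) beat_times <- cumsum(intervals)
  stopifnot(length(beat_times) == length(intervals))
  structure(list(beat_times = as.numeric(beat_times), intervals = intervals),
            class = "rr_series")
}

#' Remove the initial and final minutes of a recording
#'
#' Discards the first and last `trim` minutes to avoid settling-in and
#' wake-up artifacts. For an `ecg_record` the cut is in waveform time;
#' for an `rr_series` it is applied to the beat-time span.
#'
#' @param x An `ecg_record` or `rr_series`.
#' @param trim Minutes to remove at each end (default 15).
#' @return The trimmed object, with `start_offset` advanced for ECG.
#' @export
trim_edges <- function(x, trim = 15) UseMethod("trim_edges")

#' @export
trim_edges.ecg_record <- function(x, trim = 15) {
  dur <- length(x$samples) / x$fs
  tsec <- trim * 60
  if (dur <= 2 * tsec) stop("recording too short to trim")
  i0 <- floor(tsec * x$fs) + 1L
  i1 <- length(x$samples) - floor(tsec * x$fs)
  ecg_record(x$samples[i0:i1], x$fs, start_offset = x$start_offset + tsec)
}

#' @export
trim_edges.rr_series <- function(x, trim = 15) {
  tsec <- trim * 60
  span <- max(x$beat_times) - min(x$beat_times)
  if (span <= 2 * tsec) stop("recording too short to trim")
  lo <- min(x$beat_times) + tsec
  hi <- max(x$beat_times) - tsec
  keep <- x$beat_times >= lo & x$beat_times <= hi
  if (!any(keep)) stop("recording too short to trim")
  rr_series(x$intervals[keep], x$beat_times[keep])
}

# FFT-based analytic-signal envelope (magnitude of the analytic signal).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect R peaks in an ECG signal
#'
#' Hilbert-envelope detector: band-pass 8-20 Hz, differentiate, take the
#' magnitude of the analytic signal (which makes detection invariant to
#' polarity and overall amplitude), then apply an adaptive threshold (a
#' fraction of the running RMS of the envelope) with a 0.2 s refractory
#' period. A search-back pass re-examines abnormally long inter-peak
#' gaps at half threshold to recover missed beats.
#'
#' @param ecg An `ecg_record` with `fs >= 100` Hz and at least 10 s of
#'   signal.
#' @param threshold_frac Threshold as a fraction of the running RMS.
#' @return Integer vector of strictly increasing sample indices.
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 1.2) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  x <- ecg$samples
  if (length(x) < 10 * fs) stop("signal shorter than 10 s")
  if (stats::var(x) == 0) stop("no QRS activity")

  bf <- signal::butter(2, c(8, 20) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  dx <- c(diff(xf), 0)
  env <- analytic_envelope(dx)

  # running RMS over ~2 s windows, linearly interpolated between centers
  wlen <- max(16L, as.integer(round(2 * fs)))
  nblk <- max(1L, length(env) %/% wlen)
  centers <- (seq_len(nblk) - 0.5) * wlen
  rms <- vapply(seq_len(nblk), function(i) {
    seg <- env[((i - 1L) * wlen + 1L):min(i * wlen, length(env))]
    sqrt(mean(seg^2))
  }, numeric(1))
  thr_curve <- stats::approx(centers, rms, xout = seq_along(env),
                             rule = 2)$y * threshold_frac

  refr <- as.integer(round(0.2 * fs))
  peaks <- find_peaks_refractory(env, thr_curve, refr)
  if (length(peaks) >= 3) {
    peaks <- searchback_peaks(env, thr_curve, peaks, refr)
  }
  peaks
}

# Local-maximum picking above a threshold curve with refractory spacing.
find_peaks_refractory <- function(env, thr, refr) {
  above <- env > thr
  cand <- which(above[-c(1, length(env))] &
                  env[2:(length(env) - 1)] >= env[1:(length(env) - 2)] &
                  env[2:(length(env) - 1)] >= env[3:length(env)]) + 1L
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    if (i - last >= refr) {
      peaks <- c(peaks, i)
      last <- i
    } else if (length(peaks) && env[i] > env[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
      last <- i
    }
  }
  peaks
}

# Re-scan long inter-peak gaps at half threshold for missed beats.
searchback_peaks <- function(env, thr, peaks, refr) {
  med_gap <- stats::median(diff(peaks))
  out <- peaks
  gaps <- which(diff(peaks) > 1.66 * med_gap)
  for (g in gaps) {
    lo <- peaks[g] + refr
    hi <- peaks[g + 1] - refr
    if (hi <= lo) next
    seg <- env[lo:hi]
    j <- which.max(seg)
    if (seg[j] > 0.5 * thr[lo + j - 1L]) out <- c(out, lo + j - 1L)
  }
  sort(unique(out))
}

#' Derive RR intervals from beat times
#'
#' @param beat_times Strictly increasing R-peak times in seconds.
#' @return An `rr_series` whose intervals are the first differences of
#'   the beat times; length is one less than the number of beats.
#' @export
derive_rr <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) stop("at least two beats are required")
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  rr_series(diff(beat_times), beat_times[-1])
}

#' Reject physiologically implausible RR intervals
#'
#' Retains an interval only when (i) its duration lies in
#' `[0.33, 1.5]` s and (ii) it differs from the *previously retained*
#' interval by at most 0.66 s in absolute value. Rejected intervals
#' leave gaps in the beat-time axis (no beats are fabricated); the
#' cleaned intervals are called NN (normal-to-normal) intervals. The
#' operation is idempotent.
#'
#' @param rr An `rr_series` or numeric vector of intervals in seconds.
#' @param min_rr,max_rr Plausible duration bounds in seconds.
#' @param max_diff Maximum absolute difference from the previous
#'   retained interval, in seconds.
#' @return An object of class `nn_series` with `beat_times`,
#'   `intervals`, `n_rejected`, and `total_sleep_span` (cumulative
#'   retained interval time, seconds).
#' @export
reject_artifacts <- function(rr, min_rr = 0.33, max_rr = 1.5, max_diff = 0.66) {
  if (is.numeric(rr)) rr <- rr_series(rr)
  stopifnot(inherits(rr, c("rr_series", "nn_series")))
  x <- rr$intervals
  if (length(x) == 0) stop("empty RR series")
  keep <- logical(length(x))
  prev <- NA_real_
  for (i in seq_along(x)) {
    ok <- x[i] >= min_rr && x[i] <= max_rr &&
      (is.na(prev) || abs(x[i] - prev) <= max_diff)
    keep[i] <- ok
    if (ok) prev <- x[i]
  }
  if (!any(keep)) stop("no valid NN intervals")
  structure(
    list(beat_times = rr$beat_times[keep], intervals = x[keep],
         n_rejected = sum(!keep), total_sleep_span = sum(x[keep])),
    class = c("nn_series", "rr_series")
  )
}

#' Check that enough sleep recording remains
#'
#' Applied both before and after artifact rejection: subjects whose
#' cumulative retained interval time falls below `min_hours` are
#' excluded from analysis.
#'
#' @param nn An `nn_series` or `rr_series`.
#' @param min_hours Minimum cumulative duration in hours (default 3).
#' @return `TRUE` or `FALSE`.
#' @export
check_min_duration <- function(nn, min_hours = 3) {
  # small float tolerance so an exactly-3 h recording passes
  sum(nn$intervals) >= min_hours * 3600 - 1e-6
}

#' Uniformly sampled HRV signal container
#'
#' @param values RR values in seconds on a uniform time grid.
#' @param fs Grid sampling rate in Hz (default 3.41).
#' @param t0 Time of the first grid point in seconds.
#' @return An object of class `uniform_hrv`.
#' @export
uniform_hrv <- function(values, fs = 3.41, t0 = 0) {
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "uniform_hrv")
}

#' @export
print.uniform_hrv <- function(x, ...) {
  cat(sprintf("Uniform HRV signal: %d samples at %g Hz (%.1f min)\n",
              length(x$values), x$fs, length(x$values) / x$fs / 60))
  invisible(x)
}

#' Resample an NN tachogram onto a uniform grid
#'
#' Interpolates the tachogram (RR value versus beat time) with a cubic
#' spline (or linearly) and evaluates it on a uniform grid at `fs`,
#' enabling FFT-based spectral and bispectral analysis. Gaps created by
#' artifact rejection are spanned smoothly by the interpolant rather
#' than zero-filled, avoiding spectral discontinuity artifacts.
#'
#' @param nn An `nn_series` (or `rr_series`).
#' @param fs Target sampling rate in Hz (default 3.41).
#' @param method `"spline"` (default) or `"linear"`.
#' @return A [uniform_hrv()] object spanning the beat-time range.
#' @export
resample_uniform <- function(nn, fs = 3.41, method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(nn, c("nn_series", "rr_series")))
  tt <- nn$beat_times
  vv <- nn$intervals
  if (length(tt) < 2) stop("need at least two NN intervals to resample")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs)
  if (length(grid) == 0) stop("empty resampling grid")
  vals <- if (method == "spline") {
    stats::spline(tt, vv, xout = grid, method = "fmm")$y
  } else {
    stats::approx(tt, vv, xout = grid)$y
  }
  uniform_hrv(vals, fs = fs, t0 = grid[1])
}

#' Full pre-processing chain for one subject
#'
#' Trim edges, (for ECG input) detect R peaks and derive RR intervals,
#' reject artifacts, check the minimum-duration requirement before and
#' after rejection, and resample at `fs`.
#'
#' @param x An `ecg_record` or `rr_series`.
#' @param trim Minutes trimmed at each end.
#' @param min_hours Minimum hours of retained recording.
#' @param fs Output sampling rate in Hz.
#' @param method Interpolation method passed to [resample_uniform()].
#' @return A list with `hrv` (a `uniform_hrv`), `nn` (the `nn_series`)
#'   and `n_rejected`.
#' @export
preprocess_subject <- function(x, trim = 15, min_hours = 3, fs = 3.41,
                               method = "spline") {
  x <- trim_edges(x, trim)
  if (inherits(x, "ecg_record")) {
    pk <- detect_r_peaks(x)
    x <- derive_rr(x$start_offset + (pk - 1L) / x$fs)
  }
  if (!check_min_duration(x, min_hours)) {
    stop("recording shorter than ", min_hours, " h before artifact rejection")
  }
  nn <- reject_artifacts(x)
  if (!check_min_duration(nn, min_hours)) {
    stop("recording shorter than ", min_hours, " h after artifact rejection")
  }
  list(hrv = resample_uniform(nn, fs = fs, method = method), nn = nn,
       n_rejected = nn$n_rejected)
}
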