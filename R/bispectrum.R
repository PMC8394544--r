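# Direct (segment-averaging) bispectrum estimation for uniformly sampled
# HRV signals, with total-power normalization.

#' Segmentation plan for spectral and bispectral estimation
#'
#' Defines the windowing scheme used by [estimate_bispectrum()] and
#' [welch_psd()]: Hamming window of `window_len` samples, fractional
#' `overlap` between consecutive segments, and FFT length `nfft`
#' (zero-padded). Defaults follow standard overnight-HRV practice:
#' 1024-sample windows with 50% overlap and a 2048-point FFT, which at
#' 3.41 Hz gives a bifrequency resolution of about 0.001665 Hz.
#'
#' @param window_len Window length in samples.
#' @param overlap Fractional overlap in `[0, 1)`; 0.5 means a 512-sample
#'   hop for the default window.
#' @param nfft FFT length; must be `>= window_len`.
#' @param detrend Per-segment detrending: `"mean"` (subtract the segment
#'   mean before windowing, the default) or `"none"`.
#' @return An object of class `segment_plan`.
#' @export
segment_plan <- function(window_len = 1024L, overlap = 0.5, nfft = 2048L,
                         detrend = c("mean", "none")) {
  detrend <- match.arg(detrend)
  window_len <- as.integer(window_len)
  nfft <- as.integer(nfft)
  stopifnot(window_len >= 4L, nfft >= window_len, overlap >= 0, overlap < 1)
  step <- as.integer(round(window_len * (1 - overlap)))
  if (step < 1L) step <- 1L
  structure(
    list(window_len = window_len, overlap = overlap, nfft = nfft,
         step = step, detrend = detrend),
    class = "segment_plan"
  )
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Cut a signal into windowed, detrended segments; returns a
# window_len x nseg matrix (or errors when no full segment fits).
segment_signal <- function(x, plan) {
  n <- length(x)
  if (n < plan$window_len) {
    stop("signal shorter than one segment (", n, " < ", plan$window_len,
         " samples)")
  }
  nseg <- (n - plan$window_len) %/% plan$step + 1L
  w <- hamming_window(plan$window_len)
  starts <- (seq_len(nseg) - 1L) * plan$step
  vapply(starts, function(s) {
    seg <- x[(s + 1L):(s + plan$window_len)]
    if (plan$detrend == "mean") seg <- seg - mean(seg)
    seg * w
  }, numeric(plan$window_len))
}

new_bispectrum_matrix <- function(values, mean_abs, fs, nfft, n_segments,
                                  normalized, total_power) {
  K <- nfft %/% 2L
  structure(
    list(values = values, mean_abs = mean_abs,
         freq = (0:K) * fs / nfft, fs = fs, nfft = nfft, nyquist_bin = K,
         n_segments = n_segments, normalized = normalized,
         total_power = total_power),
    class = "bispectrum_matrix"
  )
}

#' Estimate the bispectrum of a uniformly sampled HRV signal
#'
#' Direct method: the signal is split into Hamming-windowed, mean-removed
#' segments (see [segment_plan()]); for each segment the triple product
#' `X(f1) X(f2) Conj(X(f1 + f2))` of the segment FFT is formed on the
#' first bifrequency quadrant restricted to `f1 + f2 <= f_N`, and the
#' products are averaged over segments. Independent realizations (e.g.
#' from [simulate_qpc_signal()] with `n_records > 1`) may be supplied as
#' a list, in which case each realization contributes its own segments.
#'
#' The returned matrix is unnormalized (`normalized = FALSE`); apply
#' [normalize_bispectrum()] before feature extraction.
#'
#' @param x A `uniform_hrv` object, a numeric vector, or a list of such
#'   (independent realizations averaged together).
#' @param plan A [segment_plan()].
#' @param fs Sampling rate in Hz, used when `x` is a bare numeric vector.
#' @return A `bispectrum_matrix` with complex `values` on the
#'   `(K+1) x (K+1)` grid (`K = nfft/2`), the incoherent magnitude level
#'   `mean_abs`, the frequency axis, segment count, and total bispectral
#'   power `total_power` (sum of all magnitudes over the computed grid).
#' @export
estimate_bispectrum <- function(x, plan = segment_plan(), fs = 3.41) {
  if (inherits(x, "uniform_hrv")) {
    fs <- x$fs
    x <- list(x$values)
  } else if (is.list(x)) {
    vals <- lapply(x, function(r) {
      if (inherits(r, "uniform_hrv")) { fs <<- r$fs; r$values } else as.numeric(r)
    })
    x <- vals
  } else {
    x <- list(as.numeric(x))
  }
  for (r in x) {
    if (anyNA(r)) stop("NaN/NA in input signal")
  }
  K <- plan$nfft %/% 2L
  ffts <- lapply(x, function(r) {
    segs <- segment_signal(r, plan)
    if (plan$nfft > plan$window_len) {
      segs <- rbind(segs, matrix(0, plan$nfft - plan$window_len, ncol(segs)))
    }
    stats::mvfft(segs)
  })
  X <- do.call(cbind, ffts)
  acc <- bispec_accumulate(X, K)
  B <- acc$mean
  bp <- sum(Mod(B))
  new_bispectrum_matrix(B, acc$mean_abs, fs = fs, nfft = plan$nfft,
                        n_segments = ncol(X), normalized = FALSE,
                        total_power = bp)
}

#' Normalize a bispectrum by its total bispectral power
#'
#' Divides every complex element by the scalar total power
#' `BP = sum(|B|)` taken over the whole computed grid, so that the
#' magnitudes of the result sum to one. Phases are untouched (positive
#' scalar divisor) and the operation is idempotent. The normalization
#' bounds every magnitude in `[0, 1]` and removes overall-scale
#' inter-subject variability before feature extraction.
#'
#' @param B A `bispectrum_matrix`.
#' @return The normalized `bispectrum_matrix` (`normalized = TRUE`,
#'   `total_power = 1`).
#' @export
normalize_bispectrum <- function(B) {
  stopifnot(inherits(B, "bispectrum_matrix"))
  if (isTRUE(B$normalized)) return(B)
  bp <- sum(Mod(B$values))
  if (!is.finite(bp) || bp <= 0) stop("degenerate bispectrum: total power is zero")
  B$values <- B$values / bp
  B$mean_abs <- B$mean_abs / bp
  B$normalized <- TRUE
  B$total_power <- 1
  B
}

#' Non-redundant bifrequency region (ROI)
#'
#' Enumerates the grid bins of the triangular non-redundant region
#' `0 <= f1 <= f2 <= f1 + f2 <= f_N`, which by the symmetry relations of
#' the bispectrum fully determines it.
#'
#' @param nfft FFT length defining the grid (`K = nfft/2` Nyquist bin).
#' @param fs Sampling rate in Hz.
#' @return A data frame with 0-based bin indices `k1`, `k2` and the
#'   corresponding frequencies `f1`, `f2` in Hz.
#' @export
roi_mask <- function(nfft = 2048L, fs = 3.41) {
  K <- as.integer(nfft) %/% 2L
  # enumerate k1 <= k2 with k1 + k2 <= K
  res <- do.call(rbind, lapply(0:K, function(k1) {
    k2max <- K - k1
    if (k2max < k1) return(NULL)
    cbind(k1 = k1, k2 = k1:k2max)
  }))
  df <- as.data.frame(res)
  df$f1 <- df$k1 * fs / nfft
  df$f2 <- df$k2 * fs / nfft
  df
}

#' Diagonal profile of a bispectrum
#'
#' Extracts the magnitudes along the main diagonal `B(f_k, f_k)` for
#' `f_k = 0, ..., f_N` and normalizes them by the diagonal power
#' `DP = sum(Diag)`, so that the normalized profile `DiagN` sums to one.
#' `DiagN` is the reference distribution for the relative diagonal power
#' feature ([rp_diag()]): normalizing over the *whole* diagonal lets a
#' region's share register redistributions of diagonal phase coupling
#' towards other frequency ranges.
#'
#' @param B A `bispectrum_matrix` (raw or normalized).
#' @return A list with `freq`, `diag` (magnitudes), `diag_n`
#'   (normalized), and `dp` (diagonal power).
#' @export
diagonal_profile <- function(B) {
  stopifnot(inherits(B, "bispectrum_matrix"))
  d <- Mod(diag(B$values))
  dp <- sum(d)
  if (!is.finite(dp) || dp <= 0) stop("degenerate diagonal: diagonal power is zero")
  list(freq = B$freq, diag = d, diag_n = d / dp, dp = dp)
}

#' Peak-to-background ratio and phase coherence at a bifrequency
#'
#' Diagnostics for quadratic phase coupling (QPC) at a bifrequency pair.
#' `ratio` compares the averaged bispectrum magnitude at the bin nearest
#' `(f1, f2)` with the median magnitude over the non-redundant region
#' (a coupled triad stands out by orders of magnitude). `coherence` is
#' the bin-wise ratio `|mean(B_m)| / mean(|B_m|)` over segments, in
#' `(0, 1]`: near 1 for phase-locked (coupled) triads and of order
#' `1/sqrt(M)` for `M` incoherently averaged segments when the phases
#' are uncoupled, so `coherence * sqrt(M)` of order one indicates that
#' the bin is indistinguishable from the incoherent background.
#'
#' @param B A `bispectrum_matrix`.
#' @param f1,f2 Target bifrequency in Hz.
#' @return A list with `ratio`, `coherence`, `n_segments`, and the
#'   snapped bin frequencies.
#' @export
qpc_peak_ratio <- function(B, f1, f2) {
  stopifnot(inherits(B, "bispectrum_matrix"))
  k1 <- which.min(abs(B$freq - min(f1, f2)))
  k2 <- which.min(abs(B$freq - max(f1, f2)))
  roi <- roi_mask(B$nfft, B$fs)
  mags <- Mod(B$values)[cbind(roi$k1 + 1L, roi$k2 + 1L)]
  bg <- stats::median(mags[mags > 0])
  peak <- Mod(B$values[k1, k2])
  coh <- if (B$mean_abs[k1, k2] > 0) peak / B$mean_abs[k1, k2] else 0
  list(ratio = peak / bg, coherence = coh, n_segments = B$n_segments,
       f1 = B$freq[k1], f2 = B$freq[k2])
}

#' @export
print.bispectrum_matrix <- function(x, ...) {
  cat("Bispectrum matrix (direct method)\n")
  cat(sprintf("  grid: %d x %d bins, df = %.6f Hz, Nyquist %.3f Hz\n",
              nrow(x$values), ncol(x$values), x$fs / x$nfft, max(x$freq)))
  cat(sprintf("  segments averaged: %d\n", x$n_segments))
  cat(sprintf("  normalized: %s (total power %.6g)\n",
              x$normalized, x$total_power))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with the same segmentation scheme as
#' the bispectrum estimator (Hamming window, 50% overlap by default).
#' Used for band-power checks and to locate the respiratory spectral
#' peak for the subject-adaptive region ([locate_bwres()]).
#'
#' @param x A `uniform_hrv` object or numeric vector.
#' @param plan A [segment_plan()].
#' @param fs Sampling rate in Hz when `x` is a bare vector.
#' @return A list with `freq` (Hz, up to Nyquist) and `power`
#'   (one-sided, arbitrary units).
#' @export
welch_psd <- function(x, plan = segment_plan(), fs = 3.41) {
  if (inherits(x, "uniform_hrv")) {
    fs <- x$fs
    x <- x$values
  }
  segs <- segment_signal(as.numeric(x), plan)
  if (plan$nfft > plan$window_len) {
    segs <- rbind(segs, matrix(0, plan$nfft - plan$window_len, ncol(segs)))
  }
  X <- stats::mvfft(segs)
  K <- plan$nfft %/% 2L
  p <- rowMeans(Mod(X[1:(K + 1L), , drop = FALSE])^2)
  list(freq = (0:K) * fs / plan$nfft, power = p)
}

#' Band power from a Welch spectrum
#'
#' @param psd Output of [welch_psd()].
#' @param band Numeric `c(lo, hi)` in Hz (inclusive).
#' @return Summed power in the band.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$power[sel])
}
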