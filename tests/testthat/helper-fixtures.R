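# Shared fixtures: toy bispectrum matrices built directly from
# magnitude (and optional phase) matrices, small segmentation plans,
# and a brute-force bispectrum oracle.

# Build a bispectrum_matrix from a complex or numeric matrix over a
# (K+1) x (K+1) grid, bypassing estimation. normalized is declared,
# not enforced; choose magnitudes accordingly in tests.
toy_bispectrum <- function(values, fs = 3.41, normalized = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  K <- nrow(values) - 1L
  nfft <- 2L * K
  bisphrv:::new_bispectrum_matrix(
    values = values + 0i, mean_abs = Mod(values),
    fs = fs, nfft = nfft, n_segments = 1L,
    normalized = normalized, total_power = sum(Mod(values)))
}

# A diagonal toy: magnitudes `diag_mags` at (k, k), k = 0-based, zeros
# elsewhere, on a grid large enough that all entries are inside the
# computable support.
toy_diag_bispectrum <- function(diag_mags, fs = 3.41) {
  K <- 2L * length(diag_mags)
  m <- matrix(0, K + 1L, K + 1L)
  for (i in seq_along(diag_mags)) m[i, i] <- diag_mags[i]
  toy_bispectrum(m, fs = fs)
}

# Region covering given 0-based diagonal bins on a toy grid (band in
# bin units: frequencies are k * fs / nfft).
toy_region_for_bins <- function(B, k_lo, k_hi, ...) {
  df <- B$fs / B$nfft
  band_region(bisphrv:::grid_of(B), "TOY", k_lo * df - df / 4,
              k_hi * df + df / 4, closed_upper = TRUE, ...)
}

small_plan <- function(n = 256L) segment_plan(n, overlap = 0.5, nfft = n)

# Region covering the entire computed support (both bin orders,
# k1 + k2 <= K): its total magnitude equals the normalization sum.
full_support_region <- function(B) {
  K <- B$nyquist_bin
  bins <- expand.grid(k1 = 0:K, k2 = 0:K)
  bins <- bins[bins$k1 + bins$k2 <= K, ]
  reg <- band_region(bisphrv:::grid_of(B), "ALL", 0, max(B$freq),
                     closed_upper = TRUE)
  reg$bins <- bins
  reg
}

# Brute-force direct-method bispectrum: per-segment FFT triple-product
# loop, no vectorization tricks shared with the implementation.
brute_force_bispectrum <- function(x, plan) {
  wl <- plan$window_len
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(wl - 1)) / (wl - 1))
  nseg <- (length(x) - wl) %/% plan$step + 1L
  K <- plan$nfft %/% 2L
  acc <- matrix(0 + 0i, K + 1L, K + 1L)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * plan$step + 1L):((s - 1L) * plan$step + wl)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, rep(0, plan$nfft - wl)))
    for (k1 in 0:K) {
      for (k2 in 0:K) {
        if (k1 + k2 <= K) {
          acc[k1 + 1L, k2 + 1L] <- acc[k1 + 1L, k2 + 1L] +
            X[k1 + 1L] * X[k2 + 1L] * Conj(X[k1 + k2 + 1L])
        }
      }
    }
  }
  acc / nseg
}

# A clean sinusoidal NN fixture: RR = base + amp * cos(2 pi f t),
# sampled at its own beat times, long enough for `hours` of recording.
sinusoid_nn <- function(hours = 0.5, base = 0.8, amp = 0.05, f = 0.1) {
  tt <- numeric(ceiling(hours * 3600 / (base - amp)) + 2L)
  rr <- numeric(length(tt))
  t <- 0
  i <- 0L
  while (t < hours * 3600 && i < length(tt)) {
    i <- i + 1L
    v <- base + amp * cos(2 * pi * f * t)
    t <- t + v
    tt[i] <- t
    rr[i] <- v
  }
  rr_series(rr[seq_len(i)], tt[seq_len(i)])
}
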