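# Bispectral region construction: classic HRV bands (VLF/LF/HF) and
# OSA-specific bands (BW1, BW2 and the subject-adaptive respiratory
# band BWRes), realized as bin sets on the bifrequency grid.

#' Bifrequency grid description
#'
#' @param fs Sampling rate in Hz (default 3.41).
#' @param nfft FFT length (default 2048).
#' @return A list with the frequency axis `freq` (Hz), Nyquist bin `K`,
#'   `fs` and `nfft`.
#' @export
bifrequency_grid <- function(fs = 3.41, nfft = 2048L) {
  nfft <- as.integer(nfft)
  K <- nfft %/% 2L
  list(freq = (0:K) * fs / nfft, K = K, fs = fs, nfft = nfft)
}

grid_of <- function(x) {
  if (inherits(x, "bispectrum_matrix")) {
    list(freq = x$freq, K = x$nyquist_bin, fs = x$fs, nfft = x$nfft)
  } else x
}

# Band-limited square region intersected with the non-redundant
# triangle. Band membership is half-open [lo, hi) unless closed_upper,
# which closes the top edge (used for HF at 0.4 Hz and for BWRes).
band_region <- function(grid, name, lo, hi, closed_upper = FALSE,
                        has_diagonal_features = TRUE) {
  grid <- grid_of(grid)
  f <- grid$freq
  inband <- f >= lo & (f < hi | (closed_upper & f <= hi))
  ks <- which(inband) - 1L
  bins <- NULL
  if (length(ks)) {
    bins <- expand.grid(k1 = ks, k2 = ks)
    bins <- bins[bins$k1 <= bins$k2 & bins$k1 + bins$k2 <= grid$K, ,
                 drop = FALSE]
    bins <- bins[order(bins$k1, bins$k2), , drop = FALSE]
    rownames(bins) <- NULL
  }
  diag_bins <- ks[2L * ks <= grid$K]
  structure(
    list(name = name, band = c(lo, hi), bins = bins, diag_bins = diag_bins,
         has_diagonal_features = has_diagonal_features,
         closed_upper = closed_upper, fs = grid$fs, nfft = grid$nfft),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Bispectral region %s: band [%.4g, %.4g%s Hz, %d bins (%d diagonal)%s\n",
              x$name, x$band[1], x$band[2], if (x$closed_upper) "]" else ")",
              if (is.null(x$bins)) 0L else nrow(x$bins), length(x$diag_bins),
              if (x$has_diagonal_features) "" else ", diagonal features excluded"))
  invisible(x)
}

#' Classic HRV bispectral regions
#'
#' The three regions bounded by the classic HRV frequency bands: VLF
#' (0-0.04 Hz), LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz). Each region is
#' the band-by-band square intersected with the non-redundant triangle;
#' band membership is half-open at the upper edge except for HF, whose
#' topmost edge (0.4 Hz) is closed, so the three regions are pairwise
#' disjoint.
#'
#' @param grid A [bifrequency_grid()] or `bispectrum_matrix`.
#' @return Named list of `region_spec` objects `VLF`, `LF`, `HF`.
#' @export
classic_regions <- function(grid = bifrequency_grid()) {
  list(
    VLF = band_region(grid, "VLF", 0, 0.04),
    LF = band_region(grid, "LF", 0.04, 0.15),
    HF = band_region(grid, "HF", 0.15, 0.40, closed_upper = TRUE)
  )
}

#' Static OSA-specific bispectral regions
#'
#' The two fixed OSA-specific regions: BW1 (0.001-0.005 Hz, linked to
#' sleep fragmentation) and BW2 (0.028-0.074 Hz, linked to the duration
#' of apneic events). These bands intentionally overlap the classic
#' VLF/LF bands; regions across the two families need not be disjoint.
#'
#' @param grid A [bifrequency_grid()] or `bispectrum_matrix`.
#' @return Named list of `region_spec` objects `BW1`, `BW2`.
#' @export
specific_static_regions <- function(grid = bifrequency_grid()) {
  list(
    BW1 = band_region(grid, "BW1", 0.001, 0.005),
    BW2 = band_region(grid, "BW2", 0.028, 0.074)
  )
}

#' Locate the subject-adaptive respiratory region (BWRes)
#'
#' Finds the frequency of the maximum of the Welch power spectrum of
#' the HRV signal inside the HF band (0.15-0.40 Hz, where the
#' respiratory peak lives) and builds a 0.04 Hz-wide band centered on
#' it, clipped to the physiologic respiratory range `[0.15, 0.40]` Hz.
#' Because the band tracks the respiratory peak rather than a fixed
#' range, diagonal-based features lose their harmonic-coupling meaning
#' here and are excluded (`has_diagonal_features = FALSE`).
#'
#' @param x A `uniform_hrv` object for the subject.
#' @param grid A [bifrequency_grid()] or `bispectrum_matrix`.
#' @param plan [segment_plan()] for the Welch spectrum.
#' @param hf_band Search band in Hz.
#' @param half_width Half-width of the adaptive band in Hz (default
#'   0.02, i.e. a 0.04 Hz-wide band).
#' @return A `region_spec` named `BWRes`.
#' @export
locate_bwres <- function(x, grid = bifrequency_grid(), plan = segment_plan(),
                         hf_band = c(0.15, 0.40), half_width = 0.02) {
  psd <- welch_psd(x, plan)
  sel <- psd$freq >= hf_band[1] & psd$freq <= hf_band[2]
  if (!any(sel)) stop("empty HF spectrum: no bins inside the search band")
  f_peak <- psd$freq[sel][which.max(psd$power[sel])]
  lo <- max(hf_band[1], f_peak - half_width)
  hi <- min(hf_band[2], f_peak + half_width)
  reg <- band_region(grid, "BWRes", lo, hi, closed_upper = TRUE,
                     has_diagonal_features = FALSE)
  reg$f_peak <- f_peak
  reg
}

#' All six bispectral regions for one subject
#'
#' @param x A `uniform_hrv` object (needed for the adaptive BWRes band).
#' @param grid A [bifrequency_grid()] or `bispectrum_matrix`.
#' @param plan [segment_plan()] used for the BWRes peak search.
#' @return Named list with `VLF`, `LF`, `HF`, `BW1`, `BW2`, `BWRes`.
#' @export
subject_regions <- function(x, grid = bifrequency_grid(),
                            plan = segment_plan()) {
  c(classic_regions(grid), specific_static_regions(grid),
    list(BWRes = locate_bwres(x, grid, plan)))
}
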