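# Per-region bispectral features: amplitudes, entropies, moments,
# weighted center of bispectrum, and the relative diagonal power.

LOG_FLOOR <- 1e-15

region_mags <- function(B, region) {
  if (is.null(region$bins) || nrow(region$bins) == 0) {
    stop("empty region: ", region$name)
  }
  Mod(B$values)[cbind(region$bins$k1 + 1L, region$bins$k2 + 1L)]
}

#' Amplitude features of a bispectral region
#'
#' Maximum, minimum and total magnitude of the normalized bispectrum
#' over the region's bins. The total power measures the region's share
#' of non-Gaussian (skewed) signal structure.
#'
#' @param B A normalized `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @return Named vector `c(B_max, B_min, B_total)`.
#' @export
amplitude_features <- function(B, region) {
  m <- region_mags(B, region)
  c(B_max = max(m), B_min = min(m), B_total = sum(m))
}

#' Bispectral entropies of a region
#'
#' Shannon entropy (natural log) of the region's magnitude distribution
#' raised to the power `order`: `p_j = |B_N|^i / sum(|B_N|^i)`,
#' `BE_i = -sum(p_j log p_j)` with the convention `0 log 0 = 0`.
#' Squared (`i = 2`) and cubed (`i = 3`) variants accentuate amplitude
#' differences. Values lie in `[0, log(region size)]` and grow with the
#' irregularity of the bispectral distribution.
#'
#' @param B A normalized `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @param order Power `i` in `{1, 2, 3}`.
#' @return `BE_i` in nats.
#' @export
bispectral_entropy <- function(B, region, order = 1) {
  stopifnot(order %in% 1:3)
  m <- region_mags(B, region)^order
  tot <- sum(m)
  if (tot <= 0) stop("all-zero region: ", region$name)
  p <- m / tot
  p <- p[p > 0]
  abs(-sum(p * log(p))) # abs() folds IEEE -0 from a point mass
}

#' Phase entropy of a region
#'
#' Shannon entropy of the histogram of the region's bispectral phase
#' angles over `n_bins` equal-width bins partitioning `[-pi, pi)`. Zero
#' for a fully phase-regular (harmonic, predictable) process; grows to
#' `log(n_bins)` as the phases become uniformly irregular.
#'
#' @param B A `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @param n_bins Number of histogram bins `N >= 2` (default 64).
#' @return `PE` in nats.
#' @export
phase_entropy <- function(B, region, n_bins = 64L) {
  stopifnot(n_bins >= 2)
  if (is.null(region$bins) || nrow(region$bins) == 0) {
    stop("empty region: ", region$name)
  }
  ph <- Arg(B$values)[cbind(region$bins$k1 + 1L, region$bins$k2 + 1L)]
  # Arg returns (-pi, pi]; fold +pi into the first bin of [-pi, pi)
  ph[ph >= pi] <- -pi
  bin <- floor((ph + pi) / (2 * pi) * n_bins)
  bin[bin >= n_bins] <- n_bins - 1L
  p <- tabulate(bin + 1L, nbins = n_bins) / length(ph)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Moment features of a bispectral region
#'
#' Logarithmic-magnitude sums characterizing region nonlinearity:
#' `H_1` sums `log|B_N|` over the whole region; `H_2` over the region's
#' diagonal; `H_3` and `H_4` are the first- and second-order moments of
#' the diagonal log magnitudes, with `k` the 1-based position along the
#' region's diagonal. Magnitudes are floored at `1e-15` before taking
#' logs so that underflowing normalized magnitudes keep the sums
#' finite. Diagonal moments (`H_2`-`H_4`) are excluded for regions with
#' `has_diagonal_features = FALSE` (BWRes), where `f1 = f2` bins carry
#' no harmonic-coupling meaning.
#'
#' @param B A normalized `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @param diagonal If `FALSE`, only `H_1` is returned; requesting
#'   diagonal moments for a region that excludes them is an error.
#' @return Named vector `c(H_1, H_2, H_3, H_4)` (or `H_1` alone).
#' @export
moment_features <- function(B, region, diagonal = region$has_diagonal_features) {
  m <- region_mags(B, region)
  h1 <- sum(log(pmax(m, LOG_FLOOR)))
  if (!diagonal) return(c(H_1 = h1))
  if (!region$has_diagonal_features) {
    stop("diagonal features excluded for region ", region$name)
  }
  dk <- region$diag_bins
  if (length(dk) == 0) stop("region ", region$name, " has no diagonal bins")
  dm <- Mod(B$values)[cbind(dk + 1L, dk + 1L)]
  lg <- log(pmax(dm, LOG_FLOOR))
  k <- seq_along(dk)
  h2 <- sum(lg)
  h3 <- sum(k * lg)
  h4 <- sum((k - h3)^2 * lg)
  c(H_1 = h1, H_2 = h2, H_3 = h3, H_4 = h4)
}

#' Weighted center of bispectrum (WCOB) of a region
#'
#' Magnitude-weighted centroid of the bifrequency coordinates over the
#' region's bins; summarizes where the coupling focus of the region
#' lies. Decreases indicate an activity shift towards lower
#' frequencies.
#'
#' @param B A normalized `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @return Named vector `c(f1m, f2m)` in Hz.
#' @export
wcob <- function(B, region) {
  m <- region_mags(B, region)
  tot <- sum(m)
  if (tot <= 0) stop("zero total weight in region ", region$name)
  f1 <- B$freq[region$bins$k1 + 1L]
  f2 <- B$freq[region$bins$k2 + 1L]
  c(f1m = sum(f1 * m) / tot, f2m = sum(f2 * m) / tot)
}

#' Relative power of the diagonal (RP_Diag)
#'
#' The share of the whole-diagonal bispectral magnitude that falls
#' within the region's diagonal: the full main diagonal
#' `Diag(f_k) = |B(f_k, f_k)|` is normalized by the diagonal power
#' `DP = sum(Diag)` (see [diagonal_profile()]), and `RP_Diag` is the
#' sum of the normalized profile over the region's diagonal bins, in
#' linear scale. Bounded in `[0, 1]`; because the normalization spans
#' the whole frequency range, redistribution of self-coupled
#' (`f3 = 2 f1`, `phi3 = 2 phi1`) harmonic activity between frequency
#' ranges moves mass between regions' RP_Diag values. Excluded for
#' regions without diagonal features (BWRes).
#'
#' @param B A `bispectrum_matrix`.
#' @param region A `region_spec` with `has_diagonal_features = TRUE`.
#' @return `RP_Diag` in `[0, 1]`.
#' @export
rp_diag <- function(B, region) {
  if (!region$has_diagonal_features) {
    stop("diagonal features excluded for region ", region$name)
  }
  prof <- diagonal_profile(B)
  if (length(region$diag_bins) == 0) return(0)
  sum(prof$diag_n[region$diag_bins + 1L])
}

FEATURE_ORDER <- c("RP_Diag", "B_max", "B_min", "B_total",
                   "BE_1", "BE_2", "BE_3", "PE",
                   "H_1", "H_2", "H_3", "H_4", "f1m", "f2m")
DIAGONAL_FEATURES <- c("RP_Diag", "H_2", "H_3", "H_4")

#' All features of one region
#'
#' Computes the fourteen per-region features (ten for regions whose
#' diagonal features are excluded, such as BWRes), named
#' `<Region>_<Feature>`.
#'
#' @param B A normalized `bispectrum_matrix`.
#' @param region A `region_spec`.
#' @param n_phase_bins Histogram bins for [phase_entropy()].
#' @return Named numeric vector.
#' @export
region_features <- function(B, region, n_phase_bins = 64L) {
  amp <- amplitude_features(B, region)
  out <- c(
    if (region$has_diagonal_features) c(RP_Diag = rp_diag(B, region)),
    amp,
    BE_1 = bispectral_entropy(B, region, 1),
    BE_2 = bispectral_entropy(B, region, 2),
    BE_3 = bispectral_entropy(B, region, 3),
    PE = phase_entropy(B, region, n_phase_bins),
    moment_features(B, region),
    wcob(B, region)
  )
  names(out) <- paste0(region$name, "_", names(out))
  out[paste0(region$name, "_",
             if (region$has_diagonal_features) FEATURE_ORDER
             else setdiff(FEATURE_ORDER, DIAGONAL_FEATURES))]
}

#' Column names of the two feature catalogs
#'
#' @param catalog `"classic"` (VLF/LF/HF, 42 columns) or `"specific"`
#'   (BW1/BW2/BWRes, 38 columns: BWRes excludes the four
#'   diagonal-dependent features).
#' @return Character vector of column names.
#' @export
catalog_columns <- function(catalog = c("classic", "specific")) {
  catalog <- match.arg(catalog)
  if (catalog == "classic") {
    as.vector(vapply(c("VLF", "LF", "HF"),
                     function(r) paste0(r, "_", FEATURE_ORDER),
                     character(length(FEATURE_ORDER))))
  } else {
    c(paste0("BW1_", FEATURE_ORDER), paste0("BW2_", FEATURE_ORDER),
      paste0("BWRes_", setdiff(FEATURE_ORDER, DIAGONAL_FEATURES)))
  }
}

#' Bispectral features of one subject
#'
#' Estimates and normalizes the subject's bispectrum once, constructs
#' the six regions (including the adaptive BWRes band from the Welch
#' spectrum of the same signal), and evaluates both catalogs.
#'
#' @param x A `uniform_hrv` object.
#' @param plan [segment_plan()] for the bispectrum and Welch spectrum.
#' @param n_phase_bins Histogram bins for [phase_entropy()].
#' @return A list with named vectors `classic` (42 values) and
#'   `specific` (38 values).
#' @export
subject_features <- function(x, plan = segment_plan(), n_phase_bins = 64L) {
  B <- normalize_bispectrum(estimate_bispectrum(x, plan))
  regs <- subject_regions(x, grid_of(B), plan)
  vals <- lapply(regs, function(r) region_features(B, r, n_phase_bins))
  cat_vec <- function(regions) {
    v <- unlist(vals[regions], use.names = FALSE)
    names(v) <- unlist(lapply(vals[regions], names), use.names = FALSE)
    v
  }
  list(classic = cat_vec(c("VLF", "LF", "HF")),
       specific = cat_vec(c("BW1", "BW2", "BWRes")))
}

#' Extract the feature table for a cohort
#'
#' Runs [subject_features()] on every subject and assembles the
#' subjects-by-features table with AHI, age and severity labels. Any
#' per-subject failure is reported with a warning and the subject is
#' dropped; values are never imputed.
#'
#' @param signals Named list of `uniform_hrv` objects (names are
#'   subject ids).
#' @param labels Data frame with columns `subject_id`, `ahi`, `age`
#'   (one row per subject).
#' @param catalog `"classic"`, `"specific"`, or `"both"`.
#' @param plan [segment_plan()].
#' @param n_phase_bins Histogram bins for [phase_entropy()].
#' @return A data frame with `subject_id`, `ahi`, `age`, `severity`
#'   and the catalog feature columns (42 classic and/or 38 specific).
#'   With zero subjects, an empty data frame with the full header.
#' @export
extract_feature_table <- function(signals, labels,
                                  catalog = c("both", "classic", "specific"),
                                  plan = segment_plan(), n_phase_bins = 64L) {
  catalog <- match.arg(catalog)
  cols <- switch(catalog,
                 classic = catalog_columns("classic"),
                 specific = catalog_columns("specific"),
                 both = c(catalog_columns("classic"),
                          catalog_columns("specific")))
  unl <- function(fv) {
    v <- c(if (catalog != "specific") fv$classic,
           if (catalog != "classic") fv$specific)
    v[cols]
  }
  rows <- list()
  for (sid in names(signals)) {
    fv <- tryCatch(subject_features(signals[[sid]], plan, n_phase_bins),
                   error = function(e) {
                     warning("subject ", sid, " dropped: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(fv)) rows[[sid]] <- unl(fv)
  }
  meta_cols <- c("subject_id", "ahi", "age", "severity")
  if (length(rows) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                dimnames = list(NULL, cols)))
    out <- cbind(data.frame(subject_id = character(0), ahi = numeric(0),
                            age = numeric(0), severity = character(0)),
                 out)
    return(out)
  }
  mat <- do.call(rbind, rows)
  ids <- names(rows)
  lab <- labels[match(ids, labels$subject_id), , drop = FALSE]
  out <- data.frame(subject_id = ids, ahi = lab$ahi, age = lab$age,
                    severity = as.character(severity_from_ahi(lab$ahi)),
                    mat, row.names = NULL, check.names = FALSE)
  out
}
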