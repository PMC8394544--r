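# Toy fixture: 4x4 magnitude matrix (K = 3) with a region over the
# two lowest bins; frequencies are k * fs / nfft.
toy_setup <- function(mags = NULL) {
  if (is.null(mags)) {
    mags <- matrix(0, 7, 7)
    mags[1, 1] <- 0.1; mags[1, 2] <- mags[2, 1] <- 0.3; mags[2, 2] <- 0.2
  }
  B <- toy_bispectrum(mags, normalized = TRUE)
  list(B = B, region = toy_region_for_bins(B, 0, 1))
}

test_that("amplitude features are the max, min and sum over the region", {
  s <- toy_setup()
  expect_equal(unname(amplitude_features(s$B, s$region)), c(0.3, 0.1, 0.6))
  # single-bin region
  m <- matrix(0, 7, 7); m[2, 2] <- 0.07
  B1 <- toy_bispectrum(m, normalized = TRUE)
  r1 <- toy_region_for_bins(B1, 1, 1)
  expect_equal(unname(amplitude_features(B1, r1)), c(0.07, 0.07, 0.07))
  # region spanning the whole normalized support sums to 1
  set.seed(40)
  BN <- normalize_bispectrum(estimate_bispectrum(rnorm(1024), small_plan(128L)))
  expect_equal(unname(amplitude_features(BN, full_support_region(BN))["B_total"]),
               1, tolerance = 1e-9)
})

test_that("bispectral entropies match closed forms and hand values", {
  # uniform magnitudes over 8 bins -> log 8 for every order
  m <- matrix(0, 9, 9)
  sel <- cbind(c(1, 1, 1, 1, 2, 2, 2, 3), c(1, 2, 3, 4, 2, 3, 4, 3))
  m[sel] <- 0.1; m[sel[, c(2, 1)]] <- 0.1
  B <- toy_bispectrum(m, normalized = TRUE)
  reg <- toy_region_for_bins(B, 0, 3)
  reg$bins <- as.data.frame(sel - 1L)
  names(reg$bins) <- c("k1", "k2")
  for (i in 1:3) expect_equal(bispectral_entropy(B, reg, i), log(8),
                              tolerance = 1e-12)
  # single occupied bin -> 0
  m2 <- matrix(0, 7, 7); m2[1, 2] <- m2[2, 1] <- 0.5
  B2 <- toy_bispectrum(m2, normalized = TRUE)
  reg2 <- toy_region_for_bins(B2, 0, 1)
  for (i in 1:3) expect_equal(bispectral_entropy(B2, reg2, i), 0)
  # magnitudes {2, 1, 1}: BE_1 = 1.5 log 2; BE_2 with p = {4/6, 1/6, 1/6}
  m3 <- matrix(0, 9, 9)
  m3[1, 1] <- 2; m3[1, 2] <- m3[2, 1] <- 1; m3[1, 3] <- m3[3, 1] <- 1
  B3 <- toy_bispectrum(m3)
  reg3 <- toy_region_for_bins(B3, 0, 2)
  expect_equal(nrow(reg3$bins), 6) # (0,0) (0,1) (0,2) (1,1) (1,2) (2,2)
  reg3$bins <- reg3$bins[reg3$bins$k1 == 0, ] # restrict to the 3 toy bins
  expect_equal(bispectral_entropy(B3, reg3, 1), 1.5 * log(2),
               tolerance = 1e-9)
  expect_equal(bispectral_entropy(B3, reg3, 1), 1.0397, tolerance = 1e-4)
  be2 <- -(4 / 6 * log(4 / 6) + 2 * (1 / 6) * log(1 / 6))
  expect_equal(bispectral_entropy(B3, reg3, 2), be2, tolerance = 1e-12)
  expect_equal(be2, 0.8675, tolerance = 1e-4)
})

test_that("phase entropy counts phases in equal bins of [-pi, pi)", {
  # all phases identical -> 0
  m <- matrix(0, 7, 7)
  m[1, 1] <- 1; m[1, 2] <- m[2, 1] <- 1; m[2, 2] <- 1
  B <- toy_bispectrum(m * exp(1i * 0.7))
  reg <- toy_region_for_bins(B, 0, 1)
  expect_equal(phase_entropy(B, reg, 16), 0)
  # one phase per bin, L = N -> log N
  phases <- -pi + 2 * pi * (0:3 + 0.5) / 4
  vals <- matrix(0 + 0i, 9, 9)
  put <- cbind(c(1, 1, 1, 2), c(1, 2, 3, 2))
  for (j in 1:4) {
    vals[put[j, 1], put[j, 2]] <- exp(1i * phases[j])
    vals[put[j, 2], put[j, 1]] <- exp(1i * phases[j])
  }
  B2 <- toy_bispectrum(vals)
  reg2 <- toy_region_for_bins(B2, 0, 2)
  reg2$bins <- as.data.frame(put - 1L)
  names(reg2$bins) <- c("k1", "k2")
  expect_equal(phase_entropy(B2, reg2, 4), log(4), tolerance = 1e-12)
  # hand-enumerated histogram: phases {-3, -3, 0, 0, 0, 3}, N = 4 bins
  ph6 <- c(-3, -3, 0, 0, 0, 3)
  vals3 <- matrix(0 + 0i, 11, 11)
  put3 <- cbind(rep(1, 6), 1:6)
  for (j in 1:6) {
    vals3[put3[j, 1], put3[j, 2]] <- exp(1i * ph6[j])
    vals3[put3[j, 2], put3[j, 1]] <- exp(1i * ph6[j])
  }
  B3 <- toy_bispectrum(vals3)
  reg3 <- toy_region_for_bins(B3, 0, 5)
  reg3$bins <- as.data.frame(put3 - 1L)
  names(reg3$bins) <- c("k1", "k2")
  # bins [-pi,-pi/2), [-pi/2,0), [0,pi/2), [pi/2,pi): counts 2, 0, 3, 1
  pe_expected <- -(2 / 6 * log(2 / 6) + 3 / 6 * log(3 / 6) + 1 / 6 * log(1 / 6))
  expect_equal(phase_entropy(B3, reg3, 4), pe_expected, tolerance = 1e-12)
})

test_that("moment features evaluate the diagonal log-magnitude sums", {
  # diagonal magnitudes {e^-1, e^-1}
  m <- matrix(0, 9, 9)
  m[1, 1] <- exp(-1); m[2, 2] <- exp(-1)
  B <- toy_bispectrum(m)
  reg <- toy_region_for_bins(B, 0, 1)
  reg$bins <- data.frame(k1 = c(0L, 1L), k2 = c(0L, 1L))
  mf <- moment_features(B, reg)
  expect_equal(unname(mf["H_2"]), -2)
  expect_equal(unname(mf["H_3"]), -3)
  expect_equal(unname(mf["H_4"]), -((1 + 3)^2 + (2 + 3)^2)) # -41
  # H_1 = -M when every region magnitude is e^-1
  m2 <- matrix(0, 9, 9)
  m2[1, 1] <- m2[1, 2] <- m2[2, 1] <- m2[2, 2] <- exp(-1)
  B2 <- toy_bispectrum(m2)
  reg2 <- toy_region_for_bins(B2, 0, 1)
  expect_equal(unname(moment_features(B2, reg2)["H_1"]),
               -nrow(reg2$bins))
  # BWRes-style exclusion
  reg_no <- reg; reg_no$has_diagonal_features <- FALSE
  expect_error(moment_features(B, reg_no, diagonal = TRUE), "excluded")
  expect_named(moment_features(B, reg_no), "H_1")
})

test_that("the weighted center of bispectrum is a magnitude centroid", {
  df <- 3.41 / 12 # toy grid spacing (K = 6)
  m <- matrix(0, 7, 7)
  m[2, 3] <- m[3, 2] <- 0.07 # single mass at (df, 2 df)
  B <- toy_bispectrum(m)
  reg <- toy_region_for_bins(B, 0, 4)
  w1 <- wcob(B, reg)
  expect_equal(unname(w1), c(df, 2 * df))
  # two equal masses on the diagonal -> midpoint
  m2 <- matrix(0, 7, 7); m2[2, 2] <- 0.1; m2[3, 3] <- 0.1
  w2 <- wcob(toy_bispectrum(m2), reg)
  expect_equal(unname(w2), c(1.5 * df, 1.5 * df))
  # weights {1, 3} at f1 in {df, 2 df} -> f1m = 1.75 df
  m3 <- matrix(0, 7, 7); m3[2, 2] <- 1; m3[3, 3] <- 3
  w3 <- wcob(toy_bispectrum(m3), reg)
  expect_equal(unname(w3["f1m"]), 1.75 * df)
})

test_that("relative diagonal power is the region's share of DiagN", {
  B <- toy_diag_bispectrum(c(1, 1, 2, 4))
  # region diagonal = bins 3-4 (0-based 2-3) -> (2 + 4) / 8
  reg <- toy_region_for_bins(B, 2, 3)
  expect_equal(rp_diag(B, reg), 0.75)
  # region covering the entire diagonal -> 1
  all_reg <- toy_region_for_bins(B, 0, 3)
  expect_equal(rp_diag(B, all_reg), 1)
  # band holding no diagonal mass -> 0 share
  B2 <- toy_diag_bispectrum(c(1, 2, 0, 0))
  reg2 <- toy_region_for_bins(B2, 2, 3)
  expect_equal(rp_diag(B2, reg2), 0)
  # excluded for BWRes-style regions
  regx <- reg; regx$has_diagonal_features <- FALSE
  expect_error(rp_diag(B, regx), "excluded")
})

test_that("per-subject catalogs have 42 and 38 named features", {
  set.seed(50)
  n <- 16000
  tt <- (0:(n - 1)) / 3.41
  u <- uniform_hrv(0.8 + 0.02 * cos(2 * pi * 0.05 * tt) +
                     0.02 * cos(2 * pi * 0.25 * tt) + rnorm(n, 0, 0.01))
  fv <- subject_features(u)
  expect_length(fv$classic, 42)
  expect_length(fv$specific, 38)
  expect_identical(names(fv$classic), catalog_columns("classic"))
  expect_identical(names(fv$specific), catalog_columns("specific"))
  expect_false(any(grepl("BWRes_(RP_Diag|H_[234])", names(fv$specific))))
  # entropy bounds: 0 <= BE_i <= log(region size), 0 <= PE <= log N
  B <- normalize_bispectrum(estimate_bispectrum(u))
  regs <- subject_regions(u, bisphrv:::grid_of(B))
  for (r in regs) {
    for (i in 1:3) {
      be <- bispectral_entropy(B, r, i)
      expect_gte(be, 0)
      expect_lte(be, log(nrow(r$bins)) + 1e-12)
    }
    pe <- phase_entropy(B, r, 64)
    expect_gte(pe, 0)
    expect_lte(pe, log(64))
  }
  # amplitude and WCOB invariants
  for (r in regs) {
    a <- amplitude_features(B, r)
    expect_true(a["B_min"] >= 0 && a["B_min"] <= a["B_max"] &&
                  a["B_max"] <= 1)
    w <- wcob(B, r)
    expect_true(w["f1m"] >= r$band[1] - 1e-9 && w["f1m"] <= r$band[2] + 1e-9)
    expect_true(w["f2m"] >= r$band[1] - 1e-9 && w["f2m"] <= r$band[2] + 1e-9)
  }
})

test_that("features are invariant to input amplitude scaling", {
  set.seed(51)
  n <- 12000
  tt <- (0:(n - 1)) / 3.41
  x <- 0.8 + 0.02 * cos(2 * pi * 0.05 * tt) +
    0.02 * cos(2 * pi * 0.25 * tt) + rnorm(n, 0, 0.01)
  f1 <- subject_features(uniform_hrv(x))
  f2 <- subject_features(uniform_hrv(2.5 * x))
  expect_equal(f1$classic, f2$classic, tolerance = 1e-8)
  expect_equal(f1$specific, f2$specific, tolerance = 1e-8)
})

test_that("the cohort feature table has the catalog schema", {
  # zero subjects: empty table with full headers
  empty <- extract_feature_table(list(),
                                 data.frame(subject_id = character(0),
                                            ahi = numeric(0),
                                            age = numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_identical(setdiff(names(empty),
                           c("subject_id", "ahi", "age", "severity")),
                   c(catalog_columns("classic"), catalog_columns("specific")))
  # a failing subject is dropped with a warning, not imputed
  set.seed(52)
  good <- uniform_hrv(0.8 + 0.02 * cos(2 * pi * 0.25 * (0:11999) / 3.41) +
                        rnorm(12000, 0, 0.01))
  bad <- uniform_hrv(rep(0, 500))
  labs <- data.frame(subject_id = c("g", "b"), ahi = c(2, 3), age = c(5, 6))
  expect_warning(
    tab <- extract_feature_table(list(g = good, b = bad), labs),
    "dropped")
  expect_equal(tab$subject_id, "g")
  expect_equal(tab$severity, "mild")
  expect_equal(ncol(tab), 4 + 42 + 38)
})
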