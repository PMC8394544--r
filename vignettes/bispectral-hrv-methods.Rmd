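---
title: "Bispectral HRV analysis for pediatric sleep apnea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral HRV analysis for pediatric sleep apnea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisphrv)
```

## The problem

Obstructive sleep apnea (OSA) in children alters autonomic regulation of
the heart during sleep. Heart rate variability (HRV) — the sequence of
intervals between consecutive ECG R peaks — carries the signature of
those alterations, but ordinary power-spectral analysis discards phase
relationships between frequency components and is blind to the
non-Gaussian, nonlinear structure that apneic events induce. The
bispectrum, the third-order spectrum

$$B(f_1, f_2) = X(f_1)\,X(f_2)\,X^*(f_1+f_2),$$

retains that information: it vanishes in expectation for Gaussian
signals, and a quadratically phase-coupled triad
($f_3 = f_1 + f_2$, $\varphi_3 = \varphi_1 + \varphi_2$ — a nonlinear
interaction) produces a peak at the bifrequency $(f_1, f_2)$.

`bisphrv` implements the complete analysis chain from an overnight ECG
or RR series to severity classification: pre-processing, bispectrum
estimation and normalization, band-limited bispectral regions, fourteen
features per region, fast correlation-based filter (FCBF) selection
with bootstrap voting, multi-layer perceptron (MLP) classifiers tuned
by Cohen's kappa, and a statistical evaluation battery. Severity
follows the pediatric Apnea–Hypopnea Index (AHI) convention: no OSA
below 1 event/hour, mild in [1, 5), moderate in [5, 10), severe at 10
and above, with binary classifiers at the 1, 5 and 10 e/h cutoffs.

## Pre-processing protocol

1. **Edge trimming.** The first and last 15 minutes of the recording
   are discarded (settling-in and wake-up artifacts). For RR-file input
   the cut applies to the beat-time span.
2. **R-peak detection** (`detect_r_peaks()`): band-pass 8–20 Hz,
   differentiation, and the magnitude of the analytic (Hilbert) signal
   as an envelope, thresholded adaptively at a fraction (default 1.2)
   of a running 2 s RMS with a 0.2 s refractory period and a
   half-threshold search-back over long gaps. The envelope makes
   detection invariant to polarity and overall gain. The detector's
   published structure specifies no threshold constant; 1.2 was fixed
   a priori and is exposed as an argument.
3. **Artifact rejection** (`reject_artifacts()`): an interval is
   retained only if its duration lies in [0.33, 1.5] s *and* it
   differs from the previously **retained** interval by at most
   0.66 s. The protocol sentence describing clause (ii) is ambiguous
   about whether the comparison is against the previous raw or
   previous retained interval; comparing against the retained one is
   the only reading under which a single ectopic beat cannot poison
   the rest of the night, and it makes the operation idempotent.
   Rejected intervals leave gaps — no beats are fabricated.
4. **Duration check**: at least 3 h of cumulative retained interval
   time, verified both before and after rejection.
5. **Uniform resampling** (`resample_uniform()`): the tachogram (RR
   value versus beat time) is interpolated with a cubic spline — the
   standard HRV choice; linear interpolation is available via
   `method = "linear"` — and evaluated on a uniform 3.41 Hz grid.
   Gaps from rejection are spanned smoothly by the interpolant rather
   than zero-filled, which would inject broadband artifacts.

## Bispectrum estimation

`estimate_bispectrum()` uses the direct method: Hamming windows of
$2^{10}$ samples, 50% overlap, $2^{11}$-point FFT (bifrequency
resolution $\approx 0.001665$ Hz at 3.41 Hz), per-segment mean removal
(without it the DC bin dominates the total power), and averaging of
the FFT triple product over segments on the first quadrant restricted
to $f_1 + f_2 \le f_N$. A 3 h recording yields at least 70 segments.
The estimate is written per-realization in the definition above;
windowed segment averaging is what gives the stated window/overlap
parameters meaning.

Normalization divides every element by the scalar total power
$BP = \sum |B|$. Two choices were genuinely open:

* **Normalization support.** The sum runs over the whole computed
  quadrant, not only the non-redundant triangle
  $0 \le f_1 \le f_2 \le f_1+f_2 \le f_N$ (ROI). Since the divisor is
  one global scalar, the choice rescales every feature identically and
  cannot reorder subjects; it only fixes the convention
  $\sum |B_N| = 1$.
* **No bicoherence.** Only the total-power normalization is applied;
  per-bin normalizations would change the features' meaning.

Magnitudes are bounded in [0, 1] after normalization, which removes
overall-scale physiological variability between subjects: the tests
verify that multiplying the input signal by any constant leaves every
feature unchanged.

## Regions

Six band-bounded regions are intersected with the ROI triangle:

| family | name | band (Hz) |
|---|---|---|
| classic | VLF | 0 – 0.04 |
| classic | LF | 0.04 – 0.15 |
| classic | HF | 0.15 – 0.40 |
| OSA-specific | BW1 | 0.001 – 0.005 |
| OSA-specific | BW2 | 0.028 – 0.074 |
| OSA-specific | BWRes | 0.04 Hz around the respiratory peak |

Band membership is half-open at the upper edge, with the topmost edge
of a family closed (HF at 0.40 Hz), so bins on shared boundaries are
never double-counted within a family; BW2 intentionally overlaps VLF
and LF across families. BWRes is subject-adaptive: the peak of the
Welch spectrum (same windowing as the bispectrum) inside 0.15–0.40 Hz
is located per subject and a 0.04 Hz-wide band is centered on it,
clipped to the physiologic respiratory range. Locating the peak on the
power spectrum rather than the bispectral diagonal follows the band's
origin in spectral analysis. Because the adaptive band's diagonal bins
lose their harmonic-coupling interpretation, the four
diagonal-dependent features are excluded there.

## Features

Per region (all on the normalized bispectrum, natural logs):

* **Amplitudes**: $B_{max}$, $B_{min}$, $B_{total}$.
* **Bispectral entropies** $BE_i$, $i = 1, 2, 3$: Shannon entropy of
  $p_j = |B_N|^i / \sum |B_N|^i$; squaring/cubing accentuates
  amplitude differences. The log base is unstated in the source
  convention; natural log is used (a base change only rescales).
* **Phase entropy** $PE$: entropy of the histogram of bispectral
  phases over $N$ equal bins of $[-\pi, \pi)$. $N$ is nowhere
  specified; the default is 64, configurable per call, and the closed
  forms $PE = 0$ (degenerate) and $\log N$ (uniform) anchor the tests.
* **Moments** $H_1$–$H_4$: log-magnitude sums over the region and its
  diagonal, with the diagonal index $k$ counted 1-based *within the
  region* (region-local moments; a global index would mix region
  location into the moment). Zero magnitudes are floored at $10^{-15}$
  before logs — below any physically meaningful normalized magnitude,
  keeping sums finite.
* **WCOB** $(f_{1m}, f_{2m})$: magnitude-weighted centroid of the
  region. The defining sums are written on the complex $B_N$; a
  centroid of complex weights is not a frequency, so magnitude weights
  are used, matching the weighted-center literature.
* **RP_Diag**: the share of the *whole-diagonal* magnitude mass
  falling in the region's diagonal, in linear scale. The whole-range
  normalization is the point of the feature: when OSA redistributes
  self-coupled harmonic activity toward apnea-related frequencies, the
  share moves between regions even when absolute levels vary.

Catalogs: classic = 3 regions × 14 features = 42 columns; OSA-specific
= 14 (BW1) + 14 (BW2) + 10 (BWRes) = 38 columns.

## Selection and classification

**FCBF with bootstrap voting.** Features are discretized by
equal-frequency binning into 10 bins (rank-based, hence invariant to
monotone transforms, computed within each replicate), ranked by
symmetrical uncertainty with the four-group severity label, and pruned
by the predominance test ($SU(f, g) \ge SU(f, y)$ for an already-kept
$g$). Selection runs on 1000 bootstrap replicates; features voted
strictly more than 500 times form the subset. The discretization
scheme and the label arity are unstated in the source convention; the
four-group label is used once per catalog so one subset serves all
three cutoffs, both choices configurable.

**MLP.** One hidden layer, logistic activations, one sigmoid output
(the posterior probability of the severity class), trained by `nnet`
with cross-entropy and weight decay $\lambda$. The decay penalty
follows `nnet`'s classic convention and covers *all* weights including
biases; consequently the penalty-dominated limit
($\lambda \to \infty$) is the maximum-entropy posterior 0.5 rather
than the class prevalence. The grid is $N_H \in \{2..20\} \cup
\{22, 24, .., 50\}$ crossed with $\lambda \in \{0.5, 1, .., 10\}$ —
680 combinations. Each point is scored by Cohen's kappa averaged over
bootstrap replicates, evaluated on the out-of-bag subjects (the
source procedure states only that kappa was computed; out-of-bag
evaluation avoids the optimism of resubstitution). Ties break toward
the smaller network, then the smaller decay. With a shared decay a
large network is not intrinsically penalized below a small one on
linear structure — their out-of-bag kappas coincide within noise — so
parsimony is enforced by the deterministic tie-break, not by the
score.

**Evaluation.** Sensitivity/specificity/accuracy at the 0.5 posterior
threshold; AUC by the Mann–Whitney rank identity with midranks (equal
to trapezoidal ROC integration, which the tests verify against an
independent implementation); Kruskal–Wallis group tests with ties
correction, Bonferroni-corrected within one report's feature family,
significant at adjusted $p < 0.01$; partial Spearman correlation
controlling age by the first-order formula on ranks with a $t$
approximation on $n - 3$ degrees of freedom.

## The synthetic cohort generator

No public pediatric OSA HRV cohort ships with the package, so
`simulate_cohort()` provides subjects with the statistical structure
the analysis assumes:

$$RR(t) = \overline{RR} + \sum_i a_i(\text{AHI}) \cos(2\pi f_i t +
\varphi_i) + \varepsilon,$$

sampled at beat times by integrate-and-fire (the next beat falls one
current-RR after the previous). Defaults, fixed a priori as
child-typical values: mean RR 0.8 s (75 bpm); oscillations at
0.015 Hz (VLF), 0.09 Hz (LF) and the respiratory frequency (drawn
uniformly in 0.18–0.35 Hz per subject, setting each subject's BWRes);
an apnea-cycle component at 0.05 Hz — inside the 0.028–0.074 Hz
apnea-related band — with amplitude $0.004 + 0.0018 \cdot \text{AHI}$
seconds; beat-level noise SD 0.01 s; recording length 13 000 s (the
protocol trims 15 min per end and needs 3 h after trimming, so
anything under 12 600 s errors). AHI is drawn from a four-group
mixture (18% none, 41% mild, 18% moderate, 23% severe, matching a
clinically referred population), uniform within the bounded groups
with an exponential tail above 10 e/h. Optional quadratic
phase-coupled triads, and artifact injection in three equal modes
(0.2 s short beat, 2.0 s long beat, +0.8 s jump) exercising all
rejection clauses. All randomness derives from one seed per subject,
with subject seeds derived from the cohort seed by counter.

**What the generator does and does not emulate.** It reproduces
band-limited oscillatory structure, an AHI-dependent apnea-band
component, subject-varying respiration, artifacts and phase coupling —
enough to exercise every pipeline stage and to test *directions* of
effects (e.g. BW2 relative diagonal power rising and BW2 bispectral
entropy falling with AHI, which the tests confirm at $n = 60$). It is
not a physiological model: no sleep staging, no event-level apnea
dynamics, no realistic ECG morphology (the synthetic ECG is a QRS
template on noise, sufficient for detector fixtures). Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and
sensitivity, not clinical diagnostic performance on real recordings.

## Numerical choices and degenerate inputs

* All-zero signals yield a zero bispectrum with zero total power;
  normalization refuses it explicitly, as do the diagonal profile and
  entropy computations on all-zero regions.
* `0 log 0 = 0` throughout; entropies are clamped to remove IEEE
  negative zero.
* Kappa is defined as 1 when truth and prediction are identical
  constants (observed = expected agreement = 1).
* Bootstrap replicates whose resample contains a single class are
  redrawn and counted.
* The exactly-3 h boundary passes the duration check (a small float
  tolerance).
* QPC diagnostics: a coupled triad is detected as a peak at
  $(f_1, f_2)$ orders of magnitude above the ROI median. For the
  *absence* of coupling the magnitude ratio to the ROI median is
  uninformative — with independent phases both the peak and the noise
  background shrink as $1/\sqrt{M}$ over $M$ averaged realizations —
  so `qpc_peak_ratio()` also reports the phase coherence
  $|\overline{B}| / \overline{|B|}$ at the bin, which is $\approx 1$
  under coupling and $\approx 1/\sqrt{M}$ without it.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the study's stages at
desk scale, chosen as the package's own verification sizes: 60-subject
cohorts for direction-of-effect properties, 300 subjects × 42 features
with 200 bootstrap replicates for selection recovery, 50–100
realizations for the QPC oracles, and reduced MLP grids with 10
bootstrap replicates per point for classifier sanity. The full
680-point grid and 1000-replicate defaults remain the package
defaults for real analyses.

## Known limitations

* Real-cohort diagnostic numbers require the original clinical
  recordings and are out of scope; nothing here claims clinical
  accuracy.
* EDF input is not parsed; ECG enters as numeric vectors
  (`ecg_record()`) and RR series as plain text.
* The adaptive-band construction uses the band×band square intersected
  with the ROI; when the respiratory band sits where the square
  includes diagonal bins, those bins still carry no diagonal features,
  by design.
* The MLP decay penalty covers biases (see above); with standardized
  inputs the practical effect within the 0.5–10 grid is negligible,
  but the extreme-penalty limit differs from a bias-free formulation.
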