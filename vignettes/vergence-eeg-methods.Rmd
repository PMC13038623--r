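---
title: "Vergence-EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vergence-EEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vergelab)
```

This vignette documents the models behind `vergelab`, the parameters that
matter, and the choices made where the design was genuinely open. It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The experimental structure being modelled

A subject wearing red-green glasses fuses a variable vectogram while
prism demand increases at ~2Δ/s, first in convergence (base-out) until
fusion breaks (**BO Break**), then in divergence (**BI Break**). EEG is
recorded continuously (32-channel 10-20 cap, 500 Hz) and epoched around
four behavioural events: **Convergence Start** and **Divergence Start**
(`[0, +1000]` ms after movement onset) and the two break events
(`[-1000, 0]` ms before fusion loss — the window of maximal, failing,
fusional effort). Group statistics target two regions of interest: the
frontal ROI (F3, Fz, F4; executive/oculomotor control) and the
parieto-occipital ROI (P3, Pz, P4, O1, Oz, O2; dorsal-stream disparity
processing), in the theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz)
bands.

## The synthetic cohort generator

Clinical vergence-EEG recordings are not publicly available, so the
package ships a generator whose defaults mirror a typical case-control
protocol of this kind:
two groups of 15 subjects, 500 Hz, a full 32-channel montage, one
vergence repetition per condition, 1-second analysis epochs.

**Background.** Each channel is independent Gaussian noise with a
`1/f^β` power spectrum (default `β = 1`, RMS 10 µV), synthesised in the
frequency domain with no power below 0.3 Hz (recordings are
AC-coupled). A log-periodogram regression on 60 s of background recovers
`β` within ±0.2 (tested). Real EEG additionally contains alpha peaks,
artifacts and inter-channel correlation; none of these are modelled, so
passing tests demonstrate correctness of the *pipeline*, not performance
on real recordings.

**Effects.** An `effect_spec` names a group, condition, electrode set,
frequency band, time window (relative to the lock event) and a power
multiplier. The generator scales the band-limited component of the
background inside the window, with 50 ms cosine ramps to avoid spectral
splatter. The naive gain `sqrt(multiplier)` would *under-deliver*: a
246 ms window smears band energy across its edges (a 4–8 Hz component
has an autocorrelation time comparable to the window), so the measured
in-window band-power ratio falls well short of the requested multiplier.
The gain is therefore calibrated analytically — the expected in-window
periodogram band power of the modified signal is a quadratic in the gain
whose coefficients follow from the circulant background covariance, the
band projection and the taper; solving it yields the gain that delivers
the requested *measured* ratio. Tests verify the delivered ratio with an
independent periodogram within ±25%.

**Inter-subject variability.** Each subject draws a log-normal amplitude
factor (σ = 0.2 log-units, mean-one) applied to the effect gain, making
SEM bands and cross-validation non-degenerate. Power suppression
(multiplier < 1) is not modelled and is rejected with an error.

**Output.** In-memory recordings, or EDF+C files (16-bit, ±500 µV
physical range, one annotations channel) plus a JSON ground-truth
manifest and a CSV cohort index. Header date fields are fixed constants
so identical seeds give byte-identical files.

## Preprocessing

Average reference → 50 Hz notch → 0.5–31.25 Hz band-pass →
spherical-spline channel repair → epoching. The reference-vs-filter
order follows the conventional listing; all steps are linear so the
order of reference and filters is immaterial up to numerical noise.

* **Notch**: 2nd-order IIR (RBJ biquad), quality factor 30, applied
  forward-backward; the stopband is ~1.7 Hz wide so neighbouring EEG
  rhythms are untouched.
* **Band-pass**: 4th-order Butterworth, forward-backward. At the 31.25 Hz
  edge the upper beta band is already attenuated a few dB — a property of
  the prescribed design, shared by both groups, hence harmless for group
  contrasts.
* **Bad channels** are caller-supplied (with an optional robust-variance
  detector, off by default: the flagging criterion in routine practice is
  manual). Repair uses the Perrin spherical spline of order m = 4 with
  the series truncated when terms fall below 1e-10 (≈ 20 terms; a
  fixed 7-term truncation would leave ~1e-6 residuals) and ridge
  regularisation λ = 1e-5 for denoising (λ = 0 reproduces electrode
  values exactly and is used by the interpolation tests).
* **Component-based artifact removal** is deliberately out of scope (it
  is an established external algorithm); a pluggable
  `artifact_hook(rec, hook)` keeps the chain's interface stable, and
  synthetic data are generated artifact-free.

## The wavelet transform

The complex Morlet transform follows the explicit scale-series
construction: `WT = <s, ψ_{a,b}>` with the `|a|^{-1/2}` normalisation,
scales `a_k = c/k` for `k = 1..totalscal` with `c = 2·Fc·totalscal`, so
`Fa = Fc·fs/a_k = k·fs/(2·totalscal)` — a uniform frequency axis whose
smallest scale lands exactly on `fs/2` (tested to 1e-12). `Fc` cancels
from the axis; it only moves the time/frequency resolution trade-off.

Open parameters and their defaults:

* **Mother-wavelet parameters** `Fc = 1`, bandwidth 1.5 (time-domain
  Gaussian variance in wavelet units). Unstated in the underlying
  construction; these give a mild, conventional resolution trade-off.
* **`totalscal = 512`** (~0.49 Hz spacing). Grid-level statistics in the
  tests use 160 (20 retained bins up to 31.25 Hz) to keep permutation
  loops fast; the mapping is exact at any resolution.
* **Padding**: 500 ms reflection padding per side, trimmed after the
  transform, suppressing edge artifacts of the convolution.
* Frequencies outside 0.5–31.25 Hz are computed and discarded, honouring
  the acquisition band-pass.

**Relative power.** Per time point, band power divided by total power
over the retained 0.5–31.25 Hz axis — values in [0, 1], band-wise ratios
summing to ≤ 1. This is the default measure fed to statistics and
features (absolute power is available via `measure = "power"`). Note the
arithmetic consequence, visible in tests: elevating one band's absolute
power *lowers* every other band's relative power, so a genuine theta
elevation produces a mirror-image beta/alpha deficit in ratio units.

## Cluster-mass permutation inference

Pointwise pooled-variance two-sample t statistics (`df = nA + nB − 2`;
Welch optional; paired t with sign-flip permutations for within-subject
contrasts) are thresholded at two-tailed α = 0.05; suprathreshold points
are grouped by 4-adjacency on the (frequency, time) grid, separately by
sign (channels do not enter adjacency: statistics are computed per
ROI-averaged map). Cluster mass is the sum of member t values. The null
is the distribution of the maximum |mass| over label shuffles (5000 by
default; exhaustive enumeration available and tested against an
independent oracle on 4 + 4 designs); `p = (1 + #{null ≥ |mass|}) /
(1 + n_perm)` never returns zero.

Calibration is asserted at the family level: one full-grid test per null
cohort, family-wise rejection rate within the binomial band
[0.02, 0.09] around the nominal 0.05 over 200 cohorts at 500
permutations (20 × 50 grid). Running each band as its own family would
triple the nominal rate; band-restricted tests are for targeted
hypotheses (e.g. theta recovery), the full grid for screening.

## Classification

Features come only from significant cluster extents (band × window per
ROI channel; mean relative power, or log absolute power) — or from an
explicit a-priori table when no cluster is significant, so the fallback
is always under the analyst's eyes. Nested leave-one-out CV re-fits
*everything* inside each training fold: the z-scaler (Eq. `z = (x−μ)/σ`
with training-fold μ, σ only), the t-test feature ranking (top k = 10 by
default, ties broken lexicographically for determinism), and the
classifier. Decision scores are pooled across folds into a single ROC —
in-fold standardisation makes scores comparable, and per-fold ROCs are
meaningless for single-subject test sets. AUC is the trapezoidal area;
the positive class is NSBVD throughout.

Classifiers: linear SVM (C = 1, via `e1071`), LDA with pooled covariance
and shrinkage toward the average eigenvalue when features ≥ subjects
(written in-package; cross-checked against the reference implementation
on well-posed data), and 3-NN with Euclidean distance and
training-index tie-breaking. All three are deterministic, so reports are
reproducible bit-for-bit.

The leakage guard (label-shuffled features must score at chance) and the
separability benchmark live in the acceptance tests. The benchmark
generates cohorts with a multiplier-4 frontal-theta effect and *three*
vergence repetitions per subject: with a single repetition the
band-power estimate from one 246 ms window carries irreducible
estimation noise that caps LOOCV accuracy near 0.85 regardless of the
classifier — averaging repetitions is what makes the features genuinely
linearly separable (the repetition count is a free parameter of the
protocol; the generator default remains 1).

## Clinical baseline statistics

Each continuous variable passes a Shapiro-Wilk gate per group
(α = 0.05, constants are non-normal by convention): normal → Welch's t
(unequal variances are the rule in case-control optometry), otherwise
Mann-Whitney U with midranks, tie-corrected variance, continuity
correction, and exact enumeration for n ≤ 12. Sex ratios use Pearson's
chi-square *without* Yates correction, so identical margins give exactly
χ² = 0, p = 1. The shipped reference summary table reproduces its
baseline test statistics to printed precision (tested); the power simulation
in the tests uses bounds derived from the analytic Welch power at those
effect sizes (~0.74 for the near point of convergence at n = 15 + 15),
not aspirational round numbers.

Subtype rules (convergence insufficiency/excess, divergence
insufficiency/excess, simple exo-/esophoria) are shipped as a
data-driven constraint table over signed phorias (exophoria negative)
and magnitude thresholds; a subtype whose constraints reference missing
measures is reported as non-evaluable rather than silently failed, and
blank cells in the criteria impose no constraint.

## Numerical and testing notes

* Problem sizes in the test suite: the permutation calibration uses 200
  cohorts × 500 permutations on a 20 × 50 grid; effect recovery 25
  cohorts; the separability benchmark 20 cohorts; chosen to keep the
  suite's full run in a few minutes on one CPU while leaving binomial
  margins meaningful.
* All stochastic fixtures are seeded; generator output is bit-identical
  for equal seeds (including EDF bytes).
* Known limitations: no artifact model, no inter-channel correlation or
  volume conduction in the generator, no multiplier < 1, cluster
  adjacency does not span channels, and EDF support covers the
  continuous (EDF+C) single-rate case only.
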