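---
title: "Individualized alpha-band anchoring: methods and design notes"
author: "alphaband authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized alpha-band anchoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaband)
```

## The problem and the model

Conventional EEG band analysis uses fixed band edges (e.g. alpha =
8–13 Hz) for every subject. But the alpha rhythm's frequency landmarks vary
across individuals — by age, by disease, and within the healthy range — so
fixed edges mix physiologically different rhythms across subjects. This
package implements the individualized alternative used in the prognostic
study of mild cognitive impairment (MCI): every subject's band edges are
anchored to two landmarks detected on their own spectrum.

* **IAF** (individual alpha frequency): the frequency of maximum power in
  the extended alpha range 5–14 Hz.
* **TF** (theta/alpha transition frequency): the spectral trough between
  theta and alpha activity, an estimate of where the theta and alpha
  spectra intersect; computed as the power minimum below the alpha peak.

From the anchors, subject-specific bands follow:

| band   | edges            |
|--------|------------------|
| delta  | [TF−4, TF−2)     |
| theta  | [TF−2, TF)       |
| alpha1 | [TF, mid)        |
| alpha2 | [mid, IAF)       |
| alpha3 | [IAF, IAF+2)     |

with `mid` the midpoint of the TF–IAF range. Relative power in each band is
the band's power divided by the total power over 2–45 Hz. The central
biomarker is the **alpha3/alpha2 power ratio** — upper-alpha relative to
mid-alpha power — which is elevated in MCI patients who later convert to
Alzheimer's disease. Subjects are stratified as low (ratio < 1), middle, or
high (ratio ≥ 1.17) risk; the theta/gamma ratio is carried as a companion
marker.

All detection runs on the **collapsed spectrum**: the Welch power spectral
density averaged over all 19 electrodes of the 10–20 montage. Averaging
across the scalp suppresses channel-to-channel variability and muscle
artifact, and yields a single smooth alpha peak instead of the double or
absent peaks that plague single-electrode spectra.

## The processing contract

`subjectPipeline()` fixes the stage order:

1. **Common-average re-referencing** (before artifact detection): each
   sample has the instantaneous mean over channels subtracted, so the
   spatial mean is zero.
2. **Epoching**: consecutive, non-overlapping 2-s epochs anchored at the
   first sample; a trailing partial epoch is dropped. Two seconds at any
   sampling rate gives the 0.5 Hz spectral resolution all band arithmetic
   assumes.
3. **Artifact rejection**: the study this reimplements rejected epochs by
   expert visual inspection, which is not reproducible in code. The
   package substitutes a deterministic proxy: an epoch is dropped when any
   channel's peak-to-peak amplitude exceeds 100 µV or any
   sample-to-sample step exceeds 50 µV (both configurable:
   `amp_threshold_uv`, `grad_threshold_uv`). These defaults keep clean
   synthetic recordings intact and catch the spike artifacts the generator
   can inject; they are declared proxies, not claims about the original
   study's criteria.
4. **Welch spectrum**: one Hann-windowed FFT per kept epoch, no overlap
   between segments (the segments *are* the kept epochs), averaged into a
   one-sided density. The density is normalized by the window's mean
   square, so white noise of variance σ² integrates back to σ² — this
   makes the broadband level unbiased and lets tests assert Parseval
   equality against a direct time-domain computation.
5. **Collapse**: unweighted mean of the per-channel densities.
6. **Anchor detection, bands, powers, ratios, risk group.**

## Numerical choices

**IAF search.** The maximum-power bin in [5, 14] Hz (endpoints inclusive)
among bins that are local peaks; ties break toward the higher frequency. A
monotone spectrum (no local peak) returns the in-range maximum with the
`no-alpha-peak` flag. A second local peak within 95% of the winner's power
and at least 1 Hz away raises `double-peak`. On noisy spectra small local
peaks always exist, so the `no-alpha-peak` flag is meaningful for smooth
(well-averaged or analytic) spectra; the flag semantics are exercised on
the generator's closed-form spectrum.

**TF search.** The minimum-power bin in [max(4, IAF−6), IAF−0.5] Hz; ties
break toward the lower frequency; a minimum at either end raises
`tf-at-boundary`. The source study says only "minimum power in the alpha
range"; anchoring the window to the detected IAF keeps it subject-specific
and never empty. Both window bounds are arguments.

**Midpoint snapping.** Detected anchors sit on the 0.5 Hz grid, so the
TF–IAF midpoint can fall between bins. The half-range (IAF−TF)/2 is
rounded half *up* to a 0.5 Hz multiple and added to TF. For grid-aligned
anchors this is exactly "round the midpoint half up to the grid"; for
off-grid anchors (the published cohort means TF = 6.9, IAF = 10.9) it
leaves the arithmetic untouched, reproducing the printed band edges
2.9/4.9/6.9/8.9/10.9/12.9 exactly.

**Half-open bins.** Band power sums bins in [lo, hi), and the 2–45 Hz
normalization range is itself half-open, so contiguous bands never share a
bin and relative powers are exactly additive.

**Low-TF clipping.** For a subject with TF < 6 Hz the delta band protrudes
below the 2 Hz analysis floor. The pipeline intersects each band with the
analysis range (a band entirely outside contributes zero) rather than
failing; `relativeBandPower()` keeps the strict error contract unless
`clip = TRUE`.

**Cut-off gap.** The published tertile boundaries are printed as
"middle: 1 < ratio < 1.16" but "high: ratio > 1.17", leaving
[1.16, 1.17] unassigned. Since the published high group's observed range
starts at 1.17, the package closes the gap as middle = [1.0, 1.17).

**High bands.** Beta1 [IAF+2, IAF+5), beta2 [IAF+5, 30) and gamma
[30, 45) are *not* anchored constructs of the study; they are
configuration defaults (`defaultHighBands()`), and the theta/gamma ratio
inherits this arbitrariness — results involving it depend on the gamma
edge choice.

## The statistics layer

`leveneGateAnova()` performs a one-way ANOVA — or, with covariates, a
linear model ANCOVA in which the group factor is tested by model
comparison against the covariate-only model (type-II style, the covariates
are never credited with group variance). Levene's test (mean-centred, the
SPSS default) on the raw outcome gates the post-hoc family at p < 0.05:
Games–Howell (Welch-type pairwise t referred to the studentized range)
under heterogeneous variances, pooled-MSE Bonferroni otherwise. The gate
threshold is the conventional reading; the source text states the
dependence but not the cut. Missing values are deleted listwise per
analysis, with a message.

`stepwiseDiscriminant()` reimplements SPSS-style stepwise discriminant
factor analysis with the published settings (tolerance 0.01, F-to-enter
1.0): forward entry only (no removal step is mentioned in the source), the
candidate with the largest partial F from the Wilks'-lambda decrement
enters while its tolerance — one minus its squared multiple correlation
with the entered set, on the pooled within-group covariance — stays above
the floor. The canonical solution follows (eigendecomposition of the
within/between system via a Cholesky whitening), with Bartlett χ² tests
per root, a pooled within-group factor structure matrix, and equal-prior
nearest-centroid classification evaluated by resubstitution — the source
reports no cross-validation, so resubstitution optimism is a stated
limitation, not a bug. Wilks' lambda is cross-checked against
`stats::manova` and the classification against `MASS::lda` in the test
suite; neither library stands in for the implementation.

## What the generator emulates — and what it does not

`generateEEG()` synthesizes each subject as a single shared cortical
source, scaled per channel by a posterior-dominant gain map
(`defaultGains()`; occipital 1.5, frontopolar 0.5) plus independent white
sensor noise (2 µV). The spatial gradient is essential: a spatially
uniform source would be removed exactly by common-average re-referencing.
The source is

* pink background, PSD ∝ 1/f^1.3, 8 µV RMS over 2–45 Hz — the exponent is
  in the typical eyes-closed resting range and steep enough that the
  low edge of the TF window does not undercut the theta/alpha trough;
* a theta component at TF−1.5 Hz (FWHM 1.5 Hz);
* a broad low-alpha component at IAF−1 Hz (FWHM 1.6 Hz) supplying the
  low-alpha mass real spectra carry below the peak;
* a sharp high-alpha component at IAF (FWHM 1 Hz) that defines the
  detectable peak.

Components are synthesized in the frequency domain (Hermitian random
spectra), which is distributionally equivalent to amplitude-modulated
sinusoids with Gaussian spectral envelopes and gives every component a
closed-form expected PSD. `analyticCollapsedSpectrum()` returns this
expectation — optionally convolved with the Hann window's spectral kernel,
i.e. the exact expectation of the package's Welch estimator — and serves
as the independent oracle for recovery tests. The presets
`lowRiskSubject()` and `highRiskSubject()` differ in the high-alpha
amplitude and have analytic alpha3/alpha2 ratios of 0.903 and 1.290,
matching the published low- and high-risk group means.

Not emulated: ocular/muscle artifact morphology (only amplitude spikes,
enough to exercise rejection), non-stationarity such as drowsiness drift,
inter-channel propagation delays, and any spatial structure beyond the
static gain map. A green recovery test therefore establishes that the
pipeline inverts *this* generative family at realistic SNR — not that it
handles every pathology of clinical recordings.

`generateCohort()` draws covariate/marker rows per outcome group from a
multivariate normal with the published group means and SDs for the
alpha3/alpha2 ratio, age, education and MMSE (74 subjects: 42
non-converters, 18 AD-converters, 14 non-AD-converters), truncated to
plausible ranges (MMSE ≤ 30, positive ratios and volumes). Group-wise
theta/gamma and hippocampal-volume parameters are not published per
outcome group; the defaults give both converter groups elevated
theta/gamma (matching the reported post-hoc direction) and AD-converters
the smallest hippocampi (direction of the published risk-group volumes).
The default cross-variable correlation matrix is sparse and modest
(left–right hippocampus 0.6; ratio–hippocampus −0.3; ratio–MMSE −0.2) —
enough structure to exercise the correlation analyses without asserting
unpublished effect sizes. In `mode = "recordings"` the two EEG markers are
not drawn but re-derived by generating a recording per subject and running
the full signal pipeline, so the statistics layer can be tested with or
without the signal layer in the loop.

## Test-design notes

Recovery experiments use 300-s recordings (the acquisition length of the
emulated protocol). Two spec-level expectations were reformulated to what
the stated noise level actually supports, rather than tuned until green:

* the per-subject alpha3/alpha2 ratio at 5 minutes has sampling SD ≈ 0.07,
  so the pipeline-vs-analytic comparison asserts ensemble unbiasedness at
  0.05 (and a generous per-seed envelope), not per-seed 0.05 agreement;
* two groups 5σ apart still put a subject beyond the centroid midpoint
  with probability ≈ 0.6%, so "100% resubstitution" is asserted as the
  median over replicate draws being exactly 100%, with a floor on the
  minimum.

## Known limitations

* Anchor detection is grid-argmax at 0.5 Hz resolution by design — no
  Gaussian fitting or center-of-gravity estimation.
* The `no-alpha-peak` flag is reliable only on smooth spectra (see above).
* Classification accuracy is resubstitution-based and optimistic;
  cross-validation is deliberately out of scope to mirror the reported
  analysis.
* The published cohort-level correlations and the 88.3% discriminant
  accuracy are not reproducible without the patient data, which were never
  deposited; the suite covers those claims by property-based substitutes
  (calibration, recovery, power at the published group moments).
* EDF support covers continuous 16-bit recordings with a uniform sampling
  rate; EDF+ annotations and discontinuous files are out of scope.
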