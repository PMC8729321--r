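---
title: "Partial-volume correction and early amyloid detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-volume correction and early amyloid detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amypvc)
```

This vignette explains the models implemented in `amypvc`, their
assumptions, the tunable parameters, and the design choices that were
genuinely open — in the spirit of a methods section, not a tutorial.

## 1. The measurement model

A PET image is modeled as the true tissue activity convolved with an
isotropic Gaussian point-spread function (PSF) plus noise:

\[
Y = G_{\mathrm{FWHM}} * \big( \mathrm{GM}\cdot c_{gm} +
\mathrm{WM}\cdot c_{wm} \big) + \varepsilon .
\]

`smooth_psf()` implements \(G\) as a separable, zero-padded discrete
convolution; the kernel is truncated at 4 sigma and renormalized to unit
sum, so constants are preserved away from the volume edges and the
operator is exactly linear. FWHM defaults to 8 mm, a typical harmonized
amyloid-PET resolution; it is configurable per axis.

Two voxel-based post-reconstruction corrections are implemented against
this model:

* **PVC-2 (Meltzer-type)**: \(\hat c = Y / G(\mathrm{GM}+\mathrm{WM})\),
  defined where the blurred brain probability exceeds `tau_brain` (0.3).
  It corrects dilution by CSF/background only; white-matter spill-in is
  untouched, which matters for tracers with high unspecific WM binding.
* **PVC-3 (Müller-Gärtner-type)**:
  \(\hat c = (Y - c_{wm}\, G(\mathrm{WM})) / G(\mathrm{GM})\), defined
  where \(G(\mathrm{GM}) >\) `tau_gm` (0.3), CSF assumed zero-activity.
  The scalar \(c_{wm}\) is either known (simulation truth) or estimated
  by `estimate_wm_activity()` as the mean over `wm > 0.99` eroded by
  `erosion_mm`.

Negative corrected voxels are kept, not clipped, so ROI means stay
unbiased; their fraction is reported as a QC counter.

Numerical notes. The thresholds 0.3/0.3 and the Gaussian-PSF assumption
are standard in the voxel-based PVC literature; all are exposed in the
configuration. The function-level default for `erosion_mm` is 4 mm; the
*pipeline* uses the phantom's deep-WM mask, eroded by one PSF FWHM,
because with a thin cortical ribbon a 4 mm standoff leaves a few percent
of blurred GM signal inside the sample, which makes the WM estimate
burden-dependent and partially cancels the cortical signal PVC-3 should
recover.

## 2. The digital phantom

`build_phantom()` constructs a nested-ellipsoid digital brain on a 64³
grid of 2 mm voxels (both configurable): a cortical GM ribbon of
`cortical_thickness` (default 6 mm) over a WM interior, ventricular CSF,
a thin exterior CSF shell, and a separate cerebellar GM blob that serves
as reference region. Crisp 0/1 tissue maps partition the brain support
exactly. The ribbon is tiled into six named parcels; the composite
cortical ROI is their union.

Subject-level activity (all in arbitrary activity units):

| parameter | default | meaning |
|---|---|---|
| `c_gm_ns` | 0.8 | nonspecific GM binding (shared by cerebellum) |
| `c_wm` | 2.0 | unspecific WM binding (high, florbetapir-like) |
| `k` (per parcel) | 0.6 | activity gain at full amyloid burden |
| `a_on` (per parcel) | 0.05–0.50 | burden at which the parcel starts accumulating |
| `sd_gm_ns`, `sd_wm` | 0.06, 0.08 | between-subject s.d. of the nonspecific compartments |
| `sd_spec` | 0.25 | s.d. (log) of a per-subject specific-binding factor |
| `noise_sd` | 0.05 | white noise on the blurred image |
| `field_sd`, `field_fwhm` | 0.08, 12 mm | per-subject smooth random tissue field |
| `psf_fwhm` | 8 mm | scanner resolution |

Regional uptake follows a piecewise-linear onset-ramp,
\(c_p = c_{gm,ns} + f_{spec}\, k_p \max(0, (A - a_{on,p})/(1 - a_{on,p}))\),
with the three "early" parcels (medial prefrontal, precuneus, inferior
temporal analogues) given the lowest onsets — encoding the regional
staging of cortical amyloidosis. CSF Aβ42 is a decreasing logistic in the
latent burden, \(L + (U-L)/(1+e^{s(A-A_0)})\) with \(U=2400\), \(L=450\)
pg/ml, \(A_0=0.4\), \(s=8\), under median-preserving lognormal noise
(`sigma = 0.15`), spanning the range seen in mixed normal/MCI/dementia
cohorts. Burdens are drawn from a 60%/40% mixture of Beta(1.2, 4) and
Beta(4, 1.5), mimicking such a cohort.

Calibration rationale (chosen while validating the generator, then
frozen): `k = 0.6` puts the positive/negative composite SUVR ratio near
1.7, as observed for florbetapir; with `c_gm_ns = 0.8` the WM:GM contrast
of 2.5 places the baseline cortex in the regime where net WM spill-in
*raises* the observed composite mean above truth, while a hypointense
cortex of 1.4 (the PVC comparison condition) sits in the regime where
no-PVC under-reads, PVC-2 over-reads less, and PVC-3 is unbiased. In a
vacuum-bounded phantom both regimes cannot hold at a single contrast —
near-isointense cortex (\(c_p \to c_{wm}\)) always drifts into
spill-out dominance, a geometric fact the tests respect by probing
clearly hypo- and hyper-intense conditions.

The smooth random field deserves emphasis: without it, between-subject
variability of the simulated SUVR maps collapses onto a single global
mode (each subject's WM/cerebellum ratio), the permutation distribution
of the image-wide maximum t becomes degenerate, and voxel-wise inference
behaves like a single global test — quite unlike real data, where
anatomy, registration and binding heterogeneity produce spatially
structured variability. The field (Gaussian, 12 mm correlation scale,
s.d. 0.08 on tissue) restores a realistic spatial covariance; it is part
of the noise model, so "noise-free" checks set both `noise_sd` and
`field_sd` to zero.

What the phantom does *not* emulate: anatomical folding, atrophy,
spatial normalization error, tracer kinetics, scanner-specific effects,
Poisson projection noise (noise is additive post-reconstruction). Passing
tests therefore demonstrate correctness of the algorithms and the
direction of partial-volume mechanisms, not quantitative fidelity to any
clinical cohort.

## 3. The linear fast path

Because blurring and both PVC operators are linear in the activity image
(at fixed tissue maps), every noiseless ROI mean is a linear functional
of the subject's compartment activities. `suvr_transfer()` precomputes
these coefficients once per phantom, together with the *exact* Gaussian
distribution of each ROI functional under the noise model
(\(\mathrm{Cov} = \sigma^2 \langle K w_i, K w_j\rangle\) for ROI weight
vectors \(w\), plus the analogous term for the random field). The fast
path (`compute_suvr_table_fast()`) then produces six-variant SUVR tables
for hundreds of subjects in milliseconds — verified to match the
volumetric path to machine precision without noise, and to reproduce its
ROI-level noise s.d. with noise. Replicated tabular studies
(`study_low_tertile()`) use this path; volumetric studies
(`study_detection_order()`) do not.

## 4. Association analyses

SUVR and CSF Aβ42 are z-scaled (n−1 denominator) before spline
regression so estimates are comparable across methods and references.
The spline is the continuous piecewise-linear basis
\(\{1, x, (x-k_1)_+, (x-k_2)_+\}\) with knots at the empirical tertiles
(type-7, linear-interpolation quantiles; the same rule defines tertile
membership, with ties broken by stable order). Segment slopes are
cumulative sums of basis coefficients with OLS standard errors. Knots at
or beyond the data range drop structurally degenerate columns and the
model degrades gracefully to fewer segments (ultimately simple OLS); an
interior segment without data is an error. The sliding-knot sensitivity
analysis refits on a uniform grid of 100 quantile levels from 16.6% to
the first tertile (endpoints included), holding the second knot fixed,
and records the first-segment slope.

Comparing the CSF association of two processing methods is a comparison
of *dependent* correlations sharing one variable, implemented as the
Williams t (df = n−3), with Steiger's Fisher-z Z variant as cross-check;
its Monte-Carlo type-I error at the null is verified to sit in
[0.04, 0.06] at nominal 0.05. One design point was genuinely open:
tertile membership could be computed per method or once on the standard
processing. Descriptive tertile correlations are per-method
(`tertile_correlations()`), but the method *comparison*
(`tertile_method_comparison()`) uses the standard no-PVC tertiles for
both methods, because a dependent-correlation test is only defined on a
common sample — and because per-method selection truncates each method's
own scale so sharply that the comparison would reflect selection
artifacts rather than correction quality.

## 5. Sliding-window detection

Subjects are ranked by CSF Aβ42 (descending, stable ties); the top
`round(q·n)` (nearest integer, half away from zero — reproducing the
design sizes 23/30/15/90) form the fixed reference group. Windows of `w`
subjects slide down in steps of `s`; only full windows are formed
(`1 + floor((n − ref − w)/s)`, e.g. 36 for n = 152, leaving up to `s−1`
lowest-CSF subjects unused). Each window is compared to the reference by
a voxel-wise one-sided pooled-t test on GM-masked, within-mask-smoothed
(FWHM 10 mm, kernel renormalized inside the mask so constants are
preserved and edges are not diluted) SUVR maps. Familywise error is
controlled by the permutation distribution of the image-wide maximum t —
exact under exchangeability and free of the smoothness-estimation
machinery parametric random-field corrections need — followed by
cluster-extent filtering (18-connectivity, k = 150; k should be scaled
with the analysis-mask size on other grids). The earliest detection is
the detecting window with the highest group-mean CSF. Because windows
descend the CSF scale, scanning stops at the first detection by default.

The one-sided alternative (window > reference) reflects that the
procedure looks for signal increases; a two-sided variant is a single
argument away. The 10 mm³-per-axis smoothing notation common in SPM
batch files is read as FWHM 10 mm per axis.

## 6. Problem sizes and determinism

Replicated studies use the sizes that make each property estimable at
desk scale: the Williams calibration uses 10⁴ trivariate samples of
n = 50; the familywise-error check 20 null datasets of 24³ voxels with
500 permutations; the low-tertile study 50 cohorts of n = 600 through
the fast path; the detection study 25 volumetric cohorts of n = 150 on a
48³ grid with 200 permutations per window. All randomness flows from
explicit integer seeds; per-subject noise streams are derived
deterministically, so any individual volume can be regenerated in
isolation, and a pipeline run is fully described by its resolved
configuration (emitted alongside results) and seed.

## 7. Known limitations

* The phantom's vacuum exterior exaggerates cortical spill-out relative
  to a folded cortex whose sulcal banks face each other; absolute biases
  are therefore phantom-specific even where their ordering is robust.
* The burden→CSF logistic and the onset-ramp uptake model are
  convenient monotone stand-ins, not fitted biological models; only
  directions and orderings of downstream effects should be interpreted.
* `c_wm` is a single scalar per subject; spatially varying WM binding
  (e.g. lesions) is not modeled.
* Cluster-extent k = 150 is kept as the conventional default although
  the phantom's analysis mask is smaller than a template-space brain;
  detection studies on other grids should scale it.
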