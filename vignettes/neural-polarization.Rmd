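---
title: "Measuring neural polarization with inter-subject correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural polarization with inter-subject correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarisc)
```

## The scientific question and the measure

When two people listen to the same naturalistic stimulus — here, spoken
statements about immigration — their brain activity synchronizes wherever
processing is driven by the stimulus. *Neural polarization* is the
observation that some of this synchrony is conditional on ideology: a voxel's
time course can be correlated among listeners who share an attitude while
being uncorrelated (or anti-correlated) between listeners who do not.

`polarisc` quantifies this with inter-subject correlation (ISC). For subject
$i$ at voxel $v$:

* **within-group ISC** $w_{iv}$ is the Pearson correlation between subject
  $i$'s time course and the average time course of all *other* members of
  their own attitude group (leave-one-out);
* **between-group ISC** $b_{iv}$ is the correlation with the average time
  course of *all* members of the other group;
* the per-subject **polarization score** is $d_{iv} = w_{iv} - b_{iv}$, and
  the map the inference stage consumes is its mean over subjects.

Groups come from behavior: each subject rates agreement with every statement
on a 1–5 scale, the Immigration Attitude Score (IAS) is the mean
pro-statement rating minus the mean anti-statement rating (range $-4$ to
$+4$), and the cohort is median-split into *more supportive* and *less
supportive* halves. Subjects exactly at the median are assigned in ascending
subject-id order until the sizes balance; the split is undefined (an error)
when all scores are identical.

## The synthetic cohort: what it emulates and what it does not

The imaging data this design targets cannot be redistributed, so the package
ships a generator (`generate_cohort()`) whose defaults reproduce the study
conditions: two latent groups of 20 subjects, 44 statements (22 pro, 22
anti) with mean duration 16.3 s (SD 2 s), a fixed pseudo-random presentation
order with at most two consecutive statements of the same type, a 1.5 s
pre-rating pause plus a 16–17 s randomized wash-out between statements, and
a sampling interval of TR = 1.26 s. The grid is $12^3$ voxels of 3 mm —
deliberately small; nothing in the analysis depends on brain-like geometry.

Every voxel belongs to one of three classes, and each class mixes
unit-variance components with fixed variance shares:

* **common** voxels: $\sqrt{0.3}\,c(t) + \sqrt{0.7}\,\varepsilon_i(t)$,
  where $c$ is one smooth process shared by the whole cohort;
* **polarized** voxels: $\sqrt{0.3}\,s_{g(i)}(t) + \sqrt{0.7}\,
  \varepsilon_i(t)$, where $s_1, s_2$ are independent smooth processes, one
  per latent group — the planted polarization;
* **null** voxels: pure $\varepsilon_i(t)$.

$\varepsilon_i$ is subject-specific AR(1) noise (lag-1 coefficient 0.3, a
typical residual autocorrelation after denoising at this TR). The shared
signals are Gaussian white noise smoothed with a 6 s FWHM kernel rather than
HRF-convolved event streams: the analysis is correlation-based and needs
only band-limited shared structure, not a hemodynamic shape. A polarized
region can be restricted to one narrative type, implemented by zeroing the
group component outside that type's statement frames — this is what lets
tests mirror the pro-only/anti-only analyses. The 0.3/0.3/0.7 shares give
within-group correlations around 0.5 at planted voxels after preparation,
a strong but not degenerate effect; the share setting is the single knob
recovery tests vary.

Ratings are discretized Gaussians clipped to 1..5, with group-specific
pro/anti means (4.4/1.1 and 3.8/2.2) chosen so the two groups' mean IAS land
near 3.3 and 1.6 with a median-splittable gap, matching the magnitude of the
behavioral separation the design presumes. Questionnaire items load on a
latent attitude factor (default loading 0.7); each scale's between-group
shift is calibrated at the *scale-score* level, so the planted Cohen's d
(e.g. 1.15 for the authoritarianism scale, 0.99 for multiculturalism) is
what a two-sample t test on scored scales should recover. Ground-truth
labels (latent group per subject, class per voxel) are stored in `$truth`
and are read only by tests, never by analysis stages.

The generator does *not* emulate: realistic hemodynamics, physiological
noise, spatial autocorrelation, motion artifacts in the signal (motion is
only simulated as framewise-displacement traces for the exclusion rule), or
surface geometry. A passing recovery test therefore shows the *estimator
chain* is correct under the assumed signal model — it says nothing about
robustness to structured fMRI noise.

## Preparation pipeline

`prepare_subject()` applies, in order:

1. **Nuisance regression** — per voxel, OLS residuals on an intercept plus
   22 confound columns: 6 motion parameters, their backward-difference
   derivatives (first frame 0), global signal, framewise displacement, 6
   aCompCor components (accepted as inputs, never recomputed), and
   polynomial trends of orders 1–2. The order-0 trend *is* the intercept, so
   the fitted design has 23 columns; a rank-deficient design is an error
   naming the dependent columns.
2. **High-pass filtering** at 0.01 Hz by projecting out a discrete-cosine
   basis spanning all periods longer than 100 s (plus the mean). A
   regression-style filter avoids the edge ringing an IIR filter produces on
   designs that are later cut into windows; only the cutoff is prescribed,
   the implementation is this package's choice.
3. **Statement extraction** — frames whose midpoints fall inside
   $[\mathrm{onset}, \mathrm{onset}+\mathrm{duration})$ are kept (the
   midpoint rule is unbiased where a rounding convention is unstated), each
   voxel is z-scored within each statement window separately (constant
   windows become zeros, never NaN), and windows are concatenated in
   schedule order. With the default schedule this leaves roughly 13 frames
   per statement, about 570 frames in total.

Whether filtering preceded or followed nuisance regression, and whether it
was applied before extraction, is not determinable from the source design;
the order above is fixed, documented here, and each stage is idempotent on
its own output, so a second application is harmless. Subjects with more
than 25% of framewise-displacement values above 0.5 mm are excluded
beforehand (`exclude_by_motion()`; the inequality is strict, so exactly 25%
is kept).

## Inference: sign-flip permutations and two-stage FDR

Per voxel, the observed statistic is the one-sample t of the per-subject
polarization scores. The null is built by drawing a $\pm 1$ flip for each
subject independently with probability ½ (the identity and the full flip are
admissible draws) and applying one flip vector to *all* voxels per
permutation, preserving the spatial dependence of the null; with 12 or fewer
subjects all $2^n$ flip vectors are enumerated instead. The default is
10 000 permutations. The one-sided p-value uses the add-one estimator
$p = (1 + \#\{t^\ast \ge t\})/(1 + P)$ — the raw proportion could return an
invalid $p = 0$ — and ties count toward the numerator, the conservative
choice where the convention is unstated. A two-sided option exists for
exploring negative polarization but is off by default.

Multiplicity is controlled with the two-stage adaptive step-up procedure:
stage 1 runs the linear step-up at $q' = q/(1+q)$, the number of true nulls
is estimated as $\hat m_0 = m - r_1$ from the non-rejections, and stage 2
re-runs the step-up at $q' m / \hat m_0$. Reported q-values are
Benjamini–Hochberg adjusted values scaled by $\hat m_0 (1+q)/m$, so
`q <= q_level` reproduces the two-stage rejection set exactly. On fixtures
the rejection sets match an independent implementation of the procedure,
and the adaptive set contains the plain step-up set whenever
$\hat m_0 < m$.

### A known limitation: the t on ISC scores is anticonservative

The per-subject scores $d_{iv}$ are not independent across subjects: two
same-group subjects' within-ISC values share one cross-covariance term
through the leave-one-out averages, and two cross-group subjects' between-ISC
values share one through the full other-group average. The resulting
equicorrelation is about $1/(2 n_g)$ — small per pair, but across $n = 40$
subjects it roughly doubles the variance of the mean score relative to what
the t statistic assumes. Because sign flips destroy exactly this
correlation, the permutation null is too narrow as well, and the voxel-wise
test rejects true nulls at roughly 2–3 times the nominal rate in this
package's own null simulations. This is a property of the published method
that the package reproduces deliberately; the adaptive FDR stage on top of
sharply non-null planted signal is much less affected (null-voxel
false-discovery proportions stay near zero in the recovery tests), but
voxel-wise p-values near the threshold should be read with this inflation
in mind. Approaches that would fix it — subject-level bootstrap,
linear-mixed-effects ISC models, or pairwise-ISC permutation schemes — are
out of scope here because the point of the package is the original
estimator chain.

## Peaks and peak-level statistics

Peaks are local maxima of the cohort-average difference map under
26-connectivity inside the FDR-significant mask; maxima closer than 10 mm
are merged keeping the larger value (the extraction rule is this package's
choice — the source design names peaks but not a rule — and both parameters
are configurable). Peak values are read at the single peak voxel, the
strictest reading of "peak voxel"; coordinates are reported in mm through
the affine. Two polarization summaries are emitted per peak: the average
within-minus-between difference over all subjects (reported as `d`), and
the difference between the two groups' averages — the two quantities a
reader might mean by "the peak's d" — so no ambiguity is hidden.

Downstream tests reproduce the full reporting pattern at $n = 20/20$:
one-sample t per group (df 19), two-sample group contrasts (df 38, pooled
variance — the convention under which printed t/d pairs round-trip through
$d = t\sqrt{1/n_1 + 1/n_2}$), paired cross-narrative contrasts (df 39) with
FDR over the peak family, a pooled score over a named peak set with t-based
95% CIs, a group-by-narrative mixed ANOVA whose interaction F has df
(1, 38) and equals the squared two-sample t on pro-minus-anti differences
in the balanced case, and a pooled between-group-ISC sign comparison across
two peak sets (df 78). Neural-behavioral correlations report Pearson and
Spearman with uncorrected p and with q-values corrected separately per
family; the single-item political-inclination correlation is reported
without correction, mirroring the reporting conventions of the design.

## Numerical and design choices

* Averages of correlations are plain means of R values, not Fisher-z means
  (a Fisher-z option exists but is off by default), matching the "average
  R-value map" convention.
* The whole-sample one-to-average ISC defaults to the leave-one-out
  average; including the left-out subject inflates R. Both variants are
  implemented because the published description does not disambiguate.
* Zero-variance series produce masked (NA) correlations, never zeros; the
  permutation stage drops masked voxels and carries NA through p and q.
* `power.t.test` (exact noncentral-t power) solves the minimal-detectable-
  effect equation; at the study sizes it gives 0.45 (one-sample, n = 40)
  and 0.91 (two groups of 20) at 80% power, and a Monte-Carlo power curve
  confirms the solution to within 0.02.
* Every random stage takes an explicit seed; `run_full()` derives stage
  seeds from one master seed, and two runs with the same configuration
  produce byte-identical artifact checksums (maps are written as
  uncompressed NIfTI-1 so no compressor metadata can differ).

## Problem sizes used in the tests

Unit tests run on miniature cohorts (two groups of 3, $6^3$ grids, 10
statements) where the naive triple-loop oracles are affordable. The
end-to-end recovery and calibration tests use the full study conditions —
two groups of 20, $12^3$ grid, 44 statements, about 570 concatenated frames
— with 2 000 permutations, a reduction from the 10 000 default that leaves
the minimum attainable p at $1/2001$, far below the thresholds those tests
assert. The bundled demo configuration (two groups of 6, $8^3$ grid, 20
statements, 500 permutations) exercises every stage of `run_full()` in a
few seconds and is what the README's worked example runs.
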