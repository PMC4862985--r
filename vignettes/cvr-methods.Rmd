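---
title: "CVR mapping from step-hypercapnia BOLD: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CVR mapping from step-hypercapnia BOLD: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrkit)
```

## The measurement model

Cerebrovascular reactivity (CVR) is estimated voxel by voxel as the linear
gain between the BOLD signal and end-tidal CO2 (PetCO2). For a voxel series
$S(t)$ and regressor $x(t)$ in mmHg,

$$\widehat{\mathrm{CVR}} = 100 \cdot \frac{\hat b}{S_0}, \qquad
  \hat b = \frac{\sum_t (x_t - \bar x)(S_t - \bar S)}{\sum_t (x_t - \bar x)^2},$$

in % BOLD signal change per mmHg, with fit confidence the Pearson
product-moment correlation $r(S, x)$. The model assumes an approximately
linear BOLD response over a ~10 mmHg hypercapnic excursion and no task
activity; both are standard assumptions for step-CO2 designs.

Three conventions are fixed so results are bit-reproducible:

* **Percent-change denominator.** $S_0$ is the mean signal over the
  *baseline epoch* — retained volumes whose regressor value lies within
  1 mmHg of the protocol baseline — falling back to the mean over all
  retained volumes when no baseline epoch exists. A baseline-epoch mean is
  the physiologically natural reference; a whole-run mean would mix
  hypercapnic volumes into the denominator and bias slopes down by a few
  percent.
* **Volume timestamps.** Volume $i$ (1-based) is assigned its temporal
  midpoint $t_0 + (i - 0.5)\,\mathrm{TR}$, a symmetric choice used
  consistently by the waveform sampler and the resampler.
* **Degenerate voxels.** Constant series get slope 0 and $r = 0$ with a
  `degenerate` flag (not `NA`), so ROI means never propagate NaNs; voxels
  whose $S_0$ falls below a signal floor (default $10^{-6}\times$ the
  grand-mean signal, i.e. air) are marked invalid and excluded from
  summaries.

## Stimulus protocol and the PetCO2 regressor

The default protocol is a square-wave step design: baseline 35 mmHg, two
+10 mmHg blocks of 45 s and 130 s separated by a 90 s baseline interval,
sampled at TR 2 s over 255 volumes. The 35 mmHg baseline matches typical
resting end-tidal minima in adult cohorts (group means near 34.9 mmHg);
lead-in (60 s) and tail (185 s, filling the acquisition) are not dictated
by the block design and were fixed once at values that give a stable
pre-stimulus baseline and a generous return-to-baseline segment.

Capnograph traces are reduced to one end-tidal point per breath
*automatically*: the trace is thresholded at the midpoint of its range,
each supra-threshold run is one expiratory excursion, and the end-tidal
point is the excursion maximum (last sample attaining it, i.e. end of
expiration). Peaks closer than a minimum breath interval (default 2 s,
admitting up to 30 breaths/min) are merged keeping the higher. Manual
end-tidal picking is the historical practice; an explicit algorithm makes
the choice reproducible and testable — on noiseless simulated traces it
recovers the generating plateau levels to machine precision.

Breath-wise points are carried to the TR grid by linear interpolation with
constant extrapolation beyond the first/last breath: the simplest model
consistent with a slowly varying PetCO2 target, and exact for affine
segments. No hemodynamic lag is applied by default; an optional global
integer-volume lag (search window ±5 volumes, chosen by maximising mean
in-mask $r$) is available because a one-to-two-volume transport delay is
physiologically plausible, but the default keeps the regressor aligned as
recorded.

## Quality control

The first three volumes are discarded for magnetisation equilibration.
Motion handling is censoring by deletion — corrupted volumes are removed
from both the BOLD series and the regressor, never interpolated — driven
either by an explicit censor list or by a framewise-displacement threshold
(default 0.9 mm, rotations converted on a 50 mm sphere) on six motion
parameters. At most nine volumes may be censored per run by default; the
censoring cap and the discard count are configuration, not constants.
Deletion keeps the OLS estimator unbiased on the retained volumes, and the
suite verifies censor-invariance: fitting after deletion equals fitting the
manually shortened series, and censoring spike-corrupted volumes restores
the clean-data slope exactly.

Voxel grids are matched by a token combining dimensions and voxel size
(rounded to six significant digits so float32 NIfTI headers round-trip);
any mismatch is an error. The package never resamples images implicitly.

## ROI summaries

Tissue CVR indexes are unweighted means of the slope over *valid* voxels of
GM, WM, and brain = GM ∪ WM. CSF — including the separately tracked
ventricular mask — is excluded from the brain index because ventricular
BOLD varies inversely with PetCO2 (vessel dilatation displaces CSF),
producing an apparent negative CVR that would bias a parenchymal mean.
Volumes are voxel counts times voxel volume, in cm³, independent of map
contents.

## The digital phantom

`generate_phantom()` builds a nested-box head (air margin, one-voxel CSF
rim, GM shell, WM core, central ventricle pocket) on a default
24 × 24 × 16 grid of 3.6 × 3.6 × 3 mm voxels, and synthesises each voxel as

$$S(t) = S_0\left(1 + \frac{c}{100}(x(t) - b)\right) + \delta t + \varepsilon(t),$$

with compartment gains $c$ of 0.28 (GM), 0.160 (WM), 0 (CSF rim), and
−0.10 %/mmHg (ventricle) in the healthy-control preset (0.26 / 0.1472 in
the mTBI preset), matching observed healthy tissue means, and seeded
Gaussian noise (default 1% of compartment baseline signal, i.e. temporal
SNR ≈ 100; optionally AR(1)). Drift is off by default and available as a
per-compartment slope. Because the generator and the fitter share the
linear form, a noiseless phantom is recovered *exactly* — that is the
point: it isolates implementation error from model error. What a passing
phantom test does **not** show: robustness to EPI distortion, partial
volume, perfusion nonlinearity, or real motion, none of which the phantom
models.

## The cohort generator

`generate_cohort()` draws subject records from a per-group Gaussian copula:
latent multivariate normals with a target correlation matrix, scaled to
requested marginal means/SDs. Default moments encode a two-group study of
18 controls and 25 mTBI patients (19 with follow-up): SCAT2 91.5 ± 5.7 vs
72.8 ± 10.9, tissue CVR and volume means per group, and PetCO2 extremes.
Unspecified correlations are 0. The specified control structure (SCAT2
strongly correlated with three CVR indexes, GM volume, and age at once) is
infeasible as written — the SCAT2 row's squared correlations sum past 1 —
so the matrix is projected to the nearest correlation matrix once at
construction; the projection preserves every sign and shrinks magnitudes by
~15%, and the projected matrix is the generator's declared target (tests
compare against it, not the raw requests).

Follow-up visits are correlated innovations on the visit-1 latents.
Test–retest correlations are per-variable: 0.95 for tissue volumes, 0.7
for CVR indexes and symptom scores, 0.5 for PetCO2 extremes. Anatomical
volumes are far more reproducible than functional indexes, and the
observed significance of the paired GM-volume decline (p ≈ 0.005 at
n = 19 with a ~14 cm³ mean drop) is only attainable when the paired
difference SD is ~19 cm³, implying a volume test–retest correlation near
0.92–0.95; a uniform 0.7 would leave the decline underpowered (~40%),
contradicting the phenomenon the preset is meant to encode.

Sex is assigned by exact per-group male counts (`round(n × fraction)`,
11/18 and 18/25 at default sizes), so composition percentages are exact
rather than binomially noisy. SCAT2 is clamped to [0, 100] and volumes to
positive values; SSS is left Gaussian — its control marginal (5.3 ± 10.2)
is visibly skewed in reality, and truncating at zero would distort the
mean by more than the fidelity gained. Gaussian marginals are the main
realism limitation of the generator.

## Statistical layer

Two-sided tests throughout. The Mann–Whitney U (convention: U for the
first group level, stated in the output) uses exact enumeration over all
group assignments when $\binom{n}{n_1} \le 20\,000$ — valid under ties —
the exact no-ties distribution when $n_1 n_2 \le 400$, and a tie- and
continuity-corrected normal approximation otherwise. Paired t, Pearson
correlation (pairwise-complete), and Shapiro–Wilk come from the standard
implementations. The covariate-adjusted group effect is an additive OLS
model `response ~ group + age + sex` with type-II partial F tests (for an
additive model, the drop-one F tests), sex as a two-level indicator. The
battery driver gates each group comparison on per-group Shapiro–Wilk
results at α = 0.05: Welch t when both groups pass, Mann–Whitney
otherwise. No multiple-testing correction is applied — mirroring common
practice in small cohort studies — but the report counts the tests it ran
in an attribute, so readers can discount accordingly. Degenerate entries
(zero-variance correlations, collapsed designs) yield flagged NA rows
rather than aborting the battery.

## Problem sizes used in validation

The shipped suite validates the OLS core against a per-voxel closed-form
oracle on a 6 × 6 × 4 × 60 random phantom (tolerance 1e-10), recovers the
noiseless default-geometry phantom at 255 volumes to 1e-6, checks
Mann–Whitney against exhaustive enumeration for all splits with
$n_1+n_2 \le 8$, estimates type-I error of the gate and the group test
from 1000 seeded null replicates each, and confirms that 200 seeded
study-sized cohorts reproduce the preset's qualitative structure
(negative control symptom–CVR correlation, positive in mTBI, paired GM
volume decline) in well over 80% of replicates. These sizes were chosen
as the smallest that make each property statistically unambiguous.

## Known limitations

* No slice-timing, motion registration, spatial smoothing, or distortion
  correction: masks and (if used) motion parameters are inputs, and maps
  live in the BOLD native grid.
* The lag model is a single global integer-volume shift; voxelwise or
  fractional lags are out of scope.
* The phantom's geometry is rectangular and its noise Gaussian; it
  validates the estimator, not acquisition physics.
* Cohort marginals are Gaussian (clamped where invariants demand), so
  skewed score distributions are only approximated.
* The statistics layer assumes one record per subject-visit and two
  groups; longitudinal mixed-effects modelling is out of scope.
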