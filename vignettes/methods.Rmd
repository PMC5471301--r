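---
title: "Interhemispheric DTI analysis: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric DTI analysis: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemidti)
```

## Scope and scientific question

`hemidti` implements an analysis of radiation-induced white-matter damage
in brain-tumor patients: from diffusion-weighted volumes to the global
interhemispheric fractional-anisotropy difference ΔFA, its cross-sectional
and longitudinal statistics, and voxelwise whole brain-based spatial
statistics (WBSS). Because the motivating clinical study deposited no
imaging data, the package is built around a phantom simulator whose ground
truth is known exactly; all quantitative claims in the test suite are
claims about that simulator plus the measurement chain, not about clinical
data.

## The measurement model

Each voxel's diffusion is a symmetric positive tensor $D$ (mm²/s). A
diffusion-weighted acquisition with unit gradient direction $g$ and
weighting $b$ (s/mm²) measures

$$S = S_0 \, e^{-b\, g^\top D g},$$

and magnitude MRI corrupts $S$ with Rician noise: the recorded value is
$\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$ with independent Gaussian
$\epsilon_i$. The tensor is recovered by weighted log-linear least squares
($\ln S$ regressed on the six tensor components plus intercept $\ln S_0$,
weights $S^2$ — the first-order variance correction for log-transformed
noise). We chose log-linear rather than nonlinear fitting: it is
deterministic, adequate at $b = 800$ s/mm² and SNR ≈ 20, and matches the
era of the original analysis software; the original paper does not state
its estimator, and we make no claim that this reproduces its internals.
Negative eigenvalues (possible under noise) are clamped to $10^{-12}$
mm²/s so FA stays defined — standard practice. $S_0$ is estimated jointly
as the regression intercept; the averaged b0 image is used only for
masking and registration.

From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:
FA (normalized eigenvalue dispersion in $[0,1]$), MD $=(\sum\lambda_i)/3$,
AD $=\lambda_1$, RD $=(\lambda_2+\lambda_3)/2$. FA is defined as 0 when
all eigenvalues vanish, and is 0 outside the brain mask by convention so
hemispheric averages never touch background.

## The ΔFA statistic

For a session with a tumor in one hemisphere,

$$\Delta FA = \langle FA\rangle_{\text{healthy}} -
             \langle FA\rangle_{\text{tumor side}},$$

each average over that hemisphere's voxels with $FA > 0.2$. The threshold
excludes gray matter and tumor tissue (both below 0.2), so the statistic
reflects white matter regardless of tumor size or resection state. All
four metrics (FA, MD, AD, RD) are averaged over the *same* FA-thresholded
voxel set so their deltas are comparable. A programmatic quality check
(replacing the original study's visual T2 inspection) verifies that no
surviving voxel lies inside the tumor mask; any overlap flags the session
invalid rather than silently contaminating the average.

For control sessions there is no tumor side; we compute the signed
left-minus-right difference. Signed, because the published control "noise
level" explicitly covered FA reduction *and* increase; max |ΔFA| is
reported as the primary noise summary, with the SD and the 95th percentile
of |ΔFA| alongside (the original summary convention is not stated; all
three are computed, max-abs is primary because the printed figure is
described as a bound).

Local (tumor-centered) differences use spheres of increasing radius
(default 10–60 mm in 10 mm steps — the original figure shows radius
profiles but prints no radii) clipped to the tumor hemisphere, mirrored
across the midsagittal plane for the contralateral reference. Sign
convention: contralateral minus ipsilateral, matching the global
healthy-minus-tumor orientation. The mirror is a plain reflection of the
center of mass — the simplest contralateral correspondence in the absence
of nonlinear registration.

## Alignment

Longitudinal sessions are aligned per subject in three steps: each
follow-up b0 is rigidly registered to the baseline and moved *halfway*;
the voxelwise mean of baseline and halfway-moved follow-ups forms the
subject's b0 template; every original b0 (baseline included) is then
registered fully to the template, which removes the baseline's otherwise
privileged role. Whether the original procedure moved one or both images
is not documented; the symmetric interpretation is the default
(`halfway = "symmetric"`), with `"moving-only"` available.

Registration minimizes the masked mean squared intensity difference after
median normalization, by Nelder–Mead simplex descent with perturbed
restarts (a restart is kept only if it lowers the cost, so the best cost
is non-increasing — asserted in tests). "Conjugate simplex", the name used
for the original optimizer, corresponds to no published variant we could
pin down; Nelder–Mead with restarts is our reading. The halfway split is
the exact rigid square root (half the rotation angle about the same axis,
translation solved from $(R_{1/2}+I)t_{1/2}=t$), which composes to the
full transform to machine precision and reduces to $t/2$ for pure
translations. Scalar maps are computed in native space and resampled once
with the final transform — never refit — to avoid double interpolation of
the raw DWI data. AC-PC standardization is landmark-driven (phantom
metadata or sidecar file); no automatic landmark detection.

## The phantom and its calibration

The phantom is deliberately minimal: an ellipsoidal "brain" of coherent
white matter (eigenvalues $(1.7, 0.3, 0.3)\times10^{-3}$ mm²/s, typical
adult values — the paper gives none; FA ≈ 0.80) with a smoothly varying
principal fiber direction, an isotropic tumor sphere at white-matter MD
(ground-truth FA = 0, safely below the 0.2 threshold), and background.
Default grid 48×48×24 at 2.0×2.0×2.8 mm — the clinical voxel size on a
quarter-scale matrix; the full 128×128×64 grid is a parameter away.
Radiation damage is modeled as linear blending of the affected
hemisphere's tensor toward its isotropic part,
$D' = (1-f)D + f\,\overline{\lambda} I$: monotone in $f$, FA-specific
(MD is exactly preserved, which the ΔMD ≈ 0 tests exploit), and invertible
in closed form — `calibrate_fa_reduction()` solves for $f$ so the
noiseless ΔFA equals any target, exactly, because white-matter FA is
spatially uniform. Negative targets (healthy side lower) are realized by
blending the contralateral hemisphere.

What the phantom does *not* emulate: anatomy (no gyri, no gray matter, no
template brains), partial-volume effects, eddy-current or susceptibility
distortion, multi-shell acquisitions, or spatially heterogeneous damage. A
green test therefore establishes that the *measurement chain* recovers
the *modeled* effect — not that the clinical effect itself is of any
particular size.

Noise is Rician with default $\sigma = 5$ at $S_0 = 100$ (SNR 20 — the
paper reports no scanner SNR; 20 is conservative for 1.5 T white matter,
and the resulting control ΔFA noise, ≈ 0.0007 at the desk grid, sits
comfortably under the published 0.005 bound, which is the only constraint
the paper provides). Gaussian noise is available for analytic checks. The
gradient set is a deterministic golden-section spiral (48 directions at
b = 800 s/mm² plus 4 b0 by default, 52 volumes) — reproducible without
optimization, no duplicated directions.

## Cohort presets

All generator defaults are printed values or direct arithmetic on them:

| quantity | value | origin |
|---|---|---|
| pre/without-RT ΔFA | N(0.007, 0.008), n = 10 | printed group mean ± SD |
| post-RT ΔFA | N(0.021, 0.013), n = 11 | printed group mean ± SD |
| control sessions | 13, noise bound 0.005 | printed |
| scans (pre, post) | 12, 38 | printed totals |
| Δt distribution | gamma, mean 24, SD 11, clipped [2, 111] months | printed interval statistics |
| progression slope | (0.021 − 0.007)/24 ΔFA/month | two group means at the mean interval |
| post residual SD | $\sqrt{0.013^2 - (\text{slope}\cdot 11)^2}$ | post marginal SD decomposition |

The published patient table is internally inconsistent (its per-patient
"scans without radiation" column sums to 14 against a printed total of 12);
the generator's default layout follows the printed totals and group sizes
— 18 patients, 10 contributing a pre scan, 11 a post scan, exactly the
three heavily scanned patients (11, 10 and 5 sessions) in both groups —
with per-patient scan counts and tumor sides taken from the table.

These presets were frozen before the acceptance quantities were measured
and are not tuned: the longitudinal preset yields a median Spearman
C ≈ 0.61 against the published 0.48 — inside the acceptance band, but the
residual reflects everything the scalar model ignores (per-subject
correlation of repeated scans, non-gamma interval structure), and we
report it as-is.

## Voxelwise statistics

Smoothing uses a separable Gaussian, $\sigma = \text{FWHM}/(2\sqrt{2\ln
2})$ per axis in voxel units (8 mm default, 2–3 voxel widths). At the
brain-mask boundary two renormalizations are offered, because two desirable
invariants are mutually exclusive for one linear operator: normalized
convolution $G(fm)/G(m)$ preserves constants exactly (the default and the
field standard), while the adjoint form $G(fm/G(m))$ preserves the masked
mean exactly. Both are tested on their own invariant; they agree away from
the boundary.

The voxelwise two-sample test defaults to Mann–Whitney with a Student's
t-test selectable — the original methods name the former and the results
figure the latter; the discrepancy is surfaced as an option rather than
silently resolved. Per-voxel p-values follow exactly the scalar
`mann_whitney()` rules: exact U distribution for pooled n ≤ 20 without
ties (equivalent to enumerating all labelings), tie-corrected normal
approximation with continuity correction otherwise. Multiple comparisons
use Benjamini–Hochberg step-up at α = 0.05; surviving voxels are filtered
by 26-connected component size. The clinical 512-voxel cluster threshold
refers to the full 128×128×64 matrix; on smaller grids it scales with
grid volume (floor 5) so the criterion keeps its meaning, and the literal
512 applies at full grid.

## Cohort statistics

`mann_whitney()` is exact (via the null U distribution) for pooled
samples of at most 20 without ties, else a tie-corrected normal
approximation with continuity correction; both two-sided. The exact path
is verified against a full labeling-enumeration oracle in the tests.
`spearman_cor()` rank-transforms with mid-ranks and uses exact
permutation below n = 10, a t-approximation otherwise. The
cross-sectional analysis enforces the published rule of at most one scan
per patient per group; "earliest available" is our reading of which scan
contributes (the original states only that one did). Two-sided tests
throughout, as in the original report.

## Numerical choices

- Eigenvalues by closed-form (Cardano) symmetric 3×3 solution, vectorized;
  verified against `eigen()` in tests.
- Tensor-fit normal equations solved per voxel in compiled code
  (RcppArmadillo); OLS fallback for any numerically singular voxel.
- Trilinear interpolation everywhere; out-of-field voxels are zero and
  excluded from registration costs.
- Degenerate inputs: empty masks, all-zero eigenvalue triples, constant
  samples, coincident landmarks, and sub-threshold ROIs are defined
  behaviors (error or flagged-invalid result), not crashes.
- Determinism: every stochastic entry point takes a seed;
  `simulate_dwi()` restores the caller's RNG state.

## Known limitations

- The phantom's uniform white-matter FA makes calibration exact but
  understates biological heterogeneity; pipeline bias under heterogeneous
  FA is untested.
- Rician noise induces a small FA-dependent bias (eigenvalue repulsion)
  that differs between a damaged and a healthy hemisphere; at SNR 20 and
  desk scale this stays well inside the acceptance bands, but it grows at
  lower SNR.
- Registration is rigid and intra-subject only; no deformable
  normalization, so voxelwise statistics are within-subject by design.
- The scalar longitudinal model treats scans as exchangeable across
  subjects; real repeated measures are correlated within patient.
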