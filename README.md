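# hemidti

Interhemispheric diffusion-tensor-imaging (DTI) analysis of
radiation-induced white-matter damage — with a fully synthetic,
ground-truth-bearing test bed.

## The problem

Partial brain radiation therapy for high-grade glioma damages
normal-appearing white matter progressively over years. Conventional MRI is
insensitive to this microstructural injury; DTI metrics — fractional
anisotropy (FA), and the mean/axial/radial diffusivities (MD/AD/RD) — are
not. Because the tumor itself also depresses FA locally, a robust
whole-brain marker is the **global interhemispheric FA difference**

```
ΔFA = <FA>_healthy hemisphere − <FA>_tumor hemisphere
```

where each average runs over the hemisphere's voxels with FA > 0.2 (gray
matter and tumor tissue lie below that threshold, so only white matter
contributes). FA itself derives from the diffusion tensor eigenvalues
λ1 ≥ λ2 ≥ λ3:

```
FA = sqrt( ((λ1−λ2)² + (λ1−λ3)² + (λ3−λ2)²) / (2 (λ1² + λ2² + λ3²)) )
```

In the motivating clinical cohort (18 glioma patients, 13 controls, 1.5 T,
48 diffusion directions at b = 800 s/mm² plus 4 b0 volumes), ΔFA separated
irradiated from non-irradiated patients cross-sectionally and grew with
time since radiation longitudinally, while controls bounded the measurement
noise. No imaging data were deposited, so this package pairs the analysis
pipeline with a calibrated phantom simulator: every stage is testable
against known ground truth, and the cohort generator reproduces the
published summary statistics (pre/without-RT ΔFA 0.007 ± 0.008, post-RT
0.021 ± 0.013, control noise level 0.005, Spearman C = 0.48 against months
since radiation).

## What is in the box

- **Synthetic data** — `phantom_spec()` / `build_phantom()` /
  `simulate_dwi()`: tensor-field phantoms with an isotropic tumor sphere
  (FA < 0.2), hemisphere-wide FA reduction calibrated to any target ΔFA
  (`calibrate_fa_reduction()`), and Rician acquisition noise;
  `make_longitudinal_cohort()` writes whole cohorts (NIfTI + bvec/bval +
  TSV manifest + JSON ground truth).
- **Tensor core** — `brain_mask()`, `fit_tensor()` (weighted log-linear
  least squares), `tensor_eigensystem()`, `scalar_maps()` (FA/MD/AD/RD).
- **Alignment** — `register_rigid()` (Nelder–Mead simplex on masked MSE),
  `halfway_split()` (exact symmetric halves), `build_b0_template()`
  (per-subject halfway template), `acpc_align()`.
- **ROI analysis** — `hemisphere_masks()`, `thresholded_mean()`,
  `local_deltas()` (tumor-centered mirrored spheres), `global_delta()`.
- **Cohort statistics** — `mann_whitney()` (exact for pooled n ≤ 20),
  `spearman_cor()` (exact permutation below n = 10), `noise_level()`,
  `crosssection()`, `longitudinal_correlation()`.
- **WBSS** — `smooth_volume()` (8 mm FWHM default), `voxelwise_test()`,
  `fdr_correct()` (Benjamini–Hochberg), `cluster_filter()` (512-voxel
  threshold, auto-scaled to desk grids), `wbss()`.
- **Pipeline** — `load_manifest()`, `pipeline_config()`, `run_pipeline()`,
  and a CLI at `inst/cli/hemidti.R` (subcommands `simulate`, `fit`, `roi`,
  `run-all`, `stats`).

Voxel indices are 0-based throughout; the first array axis is left–right
with the midsagittal plane at `(nx − 1) / 2`.

## Worked example

Build a phantom whose true ΔFA is exactly the published post-RT mean, scan
it with the clinical protocol, and measure:

```r
library(hemidti)
sch <- make_gradient_scheme()           # 52 volumes: 4 b0 + 48 dirs, b = 800
cal <- calibrate_fa_reduction(0.021)    # factor 0.0445
ph  <- build_phantom(phantom_spec(tumor_hemisphere = "right",
                                  fa_reduction_factor = cal$factor))
ph
#> <dti_phantom> 48x48x24 voxels at 2.0x2.0x2.8 mm; tumor: right;
#>   fa_reduction 0.04447 (right); true delta-FA = 0.02100

dwi <- simulate_dwi(ph, sch, seed = 42)           # Rician noise, SNR 20
res <- dwi_to_maps(dwi, sch, voxel_size = ph$voxel_size)
global_delta(res$maps, hemisphere_masks(res$mask), "right",
             tumor_mask = ph$tumor_mask, session_id = "demo")
#> <delta_result demo> delta_FA = 0.02044, delta_MD = -0.00000,
#>   delta_AD = 0.00004, delta_RD = -0.00002 | n = 8921 / 8264 voxels
```

The measured ΔFA (0.0204) recovers the noiseless truth (0.0210) to well
inside the control noise level; ΔMD is ~0 because the FA-reduction model
preserves mean diffusivity. The cross-sectional statistic at the published
group presets:

```r
set.seed(1)
d <- simulate_crosssection_deltas()     # n = 10 pre vs n = 11 post
mann_whitney(d$pre, d$post)
#> <group_comparison> n = 10 vs 11; mean +/- SD: 0.008058 +/- 0.006245
#>   vs 0.02503 +/- 0.01345
#>   U = 11, two-sided p = 0.00219 (normal-approximation)
```

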