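# Study-level replication drivers: run the full imaging pipeline over
# simulated cross-sectional groups and control cohorts, and scalar-level
# Monte Carlo replications of the cohort statistics.

# one subject: build a calibrated phantom, simulate, fit, measure delta-FA
pipeline_delta_for_target <- function(target_delta, tumor_hemisphere, seed,
                                      grid_shape = c(48L, 48L, 24L),
                                      voxel_size = c(2, 2, 2.8),
                                      noise_sigma = 5, s0 = 100,
                                      scheme = make_gradient_scheme()) {
  if (tumor_hemisphere == "none") {
    ps <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                       tumor_hemisphere = "none",
                       noise_sigma = noise_sigma, s0 = s0)
  } else {
    cal <- calibrate_fa_reduction(target_delta)
    red <- if (cal$hemisphere_sign > 0) tumor_hemisphere
           else setdiff(c("left", "right"), tumor_hemisphere)
    ps <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                       tumor_hemisphere = tumor_hemisphere,
                       fa_reduction_factor = cal$factor,
                       reduction_hemisphere = red,
                       noise_sigma = noise_sigma, s0 = s0)
  }
  phantom <- build_phantom(ps)
  dwi <- simulate_dwi(phantom, scheme, seed = seed)
  res <- dwi_to_maps(dwi, scheme, voxel_size = voxel_size)
  gd <- global_delta(res$maps, hemisphere_masks(res$mask), tumor_hemisphere,
                     tumor_mask = phantom$tumor_mask)
  unname(gd$delta["delta_FA"])
}

#' Pipeline-estimated delta-FA for a simulated cross-sectional group
#'
#' Draws each subject's true global delta-FA from the preset group
#' distribution (pre/without-radiation or post-radiation), realizes it as a
#' calibrated phantom with a randomly sided tumor, simulates the full
#' diffusion acquisition at default noise, and runs the complete
#' measurement chain (masking, tensor fit, scalar maps, hemisphere split,
#' FA-thresholded global delta). One value per subject.
#'
#' @param n number of subjects.
#' @param group `"pre"` or `"post"`.
#' @param seed integer seed controlling draws and acquisition noise.
#' @param grid_shape phantom grid (default desk-scale 48 x 48 x 24).
#' @param presets study presets (see [glioma_study_presets()]).
#' @return data.frame with `true_delta_fa` (noiseless target) and
#'   `delta_FA` (pipeline estimate) per subject.
#' @export
estimate_group_delta_fa <- function(n, group = c("post", "pre"), seed = 1L,
                                    grid_shape = c(48L, 48L, 24L),
                                    presets = glioma_study_presets()) {
  group <- match.arg(group)
  set.seed(seed)
  mu <- if (group == "post") presets$post_mean else presets$pre_mean
  sdv <- if (group == "post") presets$post_sd else presets$pre_sd
  targets <- stats::rnorm(n, mu, sdv)
  sides <- sample(c("left", "right"), n, replace = TRUE)
  seeds <- sample.int(2^30, n)
  est <- vapply(seq_len(n), function(i)
    pipeline_delta_for_target(targets[i], sides[i], seeds[i], grid_shape),
    numeric(1))
  data.frame(true_delta_fa = targets, delta_FA = est)
}

#' Pipeline-estimated delta-FA for simulated symmetric controls
#'
#' Control subjects carry no tumor and no hemispheric effect; the measured
#' global delta-FA (left minus right) reflects acquisition noise and the
#' measurement chain only.
#'
#' @inheritParams estimate_group_delta_fa
#' @return numeric vector of signed control delta-FA estimates.
#' @export
estimate_control_deltas <- function(n = 13L, seed = 1L,
                                    grid_shape = c(48L, 48L, 24L)) {
  set.seed(seed)
  seeds <- sample.int(2^30, n)
  vapply(seq_len(n), function(i)
    pipeline_delta_for_target(0, "none", seeds[i], grid_shape), numeric(1))
}

#' Monte Carlo replication of the cross-sectional significance test
#'
#' Draws `n_rep` scalar-level cohorts from the preset pre- and
#' post-radiation delta-FA distributions and runs [mann_whitney()] on each.
#'
#' @param n_rep number of replicate cohorts.
#' @param seed integer seed.
#' @param presets study presets.
#' @return numeric vector of two-sided p-values (length `n_rep`).
#' @export
replicate_crosssection_p <- function(n_rep = 500L, seed = 1L,
                                     presets = glioma_study_presets()) {
  set.seed(seed)
  vapply(seq_len(n_rep), function(i) {
    d <- simulate_crosssection_deltas(presets = presets)
    mann_whitney(d$pre, d$post)$p
  }, numeric(1))
}

#' Monte Carlo replication of the longitudinal Spearman correlation
#'
#' Simulates `n_rep` cohorts of 50 (delta-t, delta-FA) scan pairs with the
#' preset longitudinal progression model and computes the Spearman
#' correlation of each.
#'
#' @param n_rep number of replicate cohorts.
#' @param seed integer seed.
#' @param presets study presets.
#' @return numeric vector of Spearman coefficients (length `n_rep`).
#' @export
replicate_longitudinal_C <- function(n_rep = 500L, seed = 1L,
                                     presets = glioma_study_presets()) {
  set.seed(seed)
  vapply(seq_len(n_rep), function(i) {
    d <- simulate_longitudinal_deltas(presets = presets)
    spearman_cor(d$delta_t_months, d$delta_FA)$C
  }, numeric(1))
}
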