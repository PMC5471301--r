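test_that("gradient schemes have the advertised structure", {
  sch <- make_gradient_scheme(48, 800, 4)
  expect_length(sch$bvalues, 52L)          # clinical protocol: 52 volumes
  expect_equal(sch$n_b0, 4L)

  sch6 <- make_gradient_scheme(6, 800, 1)
  expect_length(sch6$bvalues, 7L)
  nz <- sch6$bvalues > 0
  expect_equal(sqrt(rowSums(sch6$directions[nz, ]^2)), rep(1, 6), tolerance = 1e-9)

  expect_error(make_gradient_scheme(5), "at least 6")
})

test_that("no gradient scheme contains duplicated directions", {
  for (n in c(6L, 12L, 48L, 64L)) {
    d <- make_gradient_scheme(n)$directions
    d <- d[rowSums(d^2) > 0, ]
    dots <- tcrossprod(d)
    diag(dots) <- -Inf
    expect_lt(max(dots), 1 - 1e-6)
  }
})

test_that("symmetric phantoms have (near) zero true delta-FA", {
  ph <- small_phantom()
  expect_lt(abs(ph$true_global_delta_fa), 1e-10)
})

test_that("tumor voxels are below the white-matter FA threshold", {
  ph <- small_phantom(tumor = "right", f = 0.05)
  expect_true(any(ph$tumor_mask))
  expect_true(all(ph$true_fa[ph$tumor_mask] < 0.2))
})

test_that("true delta-FA matches a brute-force voxel-loop recomputation", {
  ph <- small_phantom(tumor = "right", f = 0.1)
  oracle <- bruteforce_delta(ph$true_fa, ph$hemispheres, "left", "right")
  expect_equal(ph$true_global_delta_fa, oracle, tolerance = 1e-10)
})

test_that("true delta-FA is recomputable from the stored tensor field", {
  ph <- small_phantom(tumor = "left", f = 0.07)
  vx <- which(ph$tissue > 0)
  ev <- hemidti:::eigvals_sym3(ph$tensor[vx, ])
  fa <- array(0, dim = ph$grid_shape)
  fa[vx] <- fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
  recomputed <- bruteforce_delta(fa, ph$hemispheres, "right", "left")
  expect_equal(ph$true_global_delta_fa, recomputed, tolerance = 1e-10)
})

test_that("increasing the reduction factor strictly increases delta-FA", {
  deltas <- vapply(c(0.02, 0.05, 0.1, 0.2),
                   function(f) small_phantom(tumor = "right", f = f)$true_global_delta_fa,
                   numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("a tumor overlapping the midline is rejected", {
  expect_error(
    build_phantom(phantom_spec(grid_shape = c(16L, 16L, 8L),
                               tumor_hemisphere = "right",
                               tumor_center = c(8.5, 7.5, 3.5),
                               tumor_radius = 10)),
    "midsagittal")
})

test_that("calibration inverts the blending model", {
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  for (target in c(0.005, 0.021, -0.01)) {
    cal <- calibrate_fa_reduction(target, lam)
    achieved <- blended_fa(0, lam) - blended_fa(cal$factor, lam)
    expect_equal(achieved, abs(target), tolerance = 1e-9)
    expect_equal(cal$hemisphere_sign, sign(target))
  }
  expect_error(calibrate_fa_reduction(0.9, lam), "exceeds")
})

test_that("noiseless signal follows the closed-form tensor model", {
  ph <- small_phantom()
  sch <- small_scheme()
  dwi <- simulate_dwi(ph, sch, noise_sigma = 0)
  # b0 volume equals S0 inside tissue
  b0 <- dwi[, , , 1]
  expect_equal(b0[ph$tissue > 0], rep(ph$s0, sum(ph$tissue > 0)))
  # all noiseless signals in (0, S0]
  sig <- dwi[rep(ph$tissue > 0, length(sch$bvalues))]
  expect_true(all(sig > 0 & sig <= ph$s0 + 1e-12))
  # isotropic voxel: S = S0 exp(-b d) for every direction
  phT <- small_phantom(tumor = "right", radius = 6)
  vx <- which(phT$tissue == 2L)[1L]
  d <- phT$tensor[vx, 1]                     # isotropic: Dxx = ADC
  dwiT <- simulate_dwi(phT, sch, noise_sigma = 0)
  V <- prod(phT$grid_shape)
  sig_vox <- matrix(dwiT, nrow = V)[vx, ]
  expect_equal(sig_vox, phT$s0 * exp(-sch$bvalues * d), tolerance = 1e-12)
})

test_that("simulation is reproducible given a seed and noiseless without one", {
  ph <- small_phantom()
  sch <- small_scheme()
  expect_identical(simulate_dwi(ph, sch, seed = 11), simulate_dwi(ph, sch, seed = 11))
  expect_false(identical(simulate_dwi(ph, sch, seed = 11), simulate_dwi(ph, sch, seed = 12)))
  expect_identical(simulate_dwi(ph, sch, noise_sigma = 0),
                   simulate_dwi(ph, sch, noise_sigma = 0, seed = 5))
  expect_error(simulate_dwi(ph, sch, noise_sigma = -1), "nonnegative")
})

test_that("Rician noise bias on b0 is under 2 percent at SNR > 10", {
  ph <- small_phantom(grid = c(8L, 8L, 8L))
  sch <- make_gradient_scheme(6, 800, 1)
  vx <- which(ph$tissue > 0L)[1:20]
  V <- prod(ph$grid_shape)
  sims <- vapply(1:400, function(s) {
    dwi <- simulate_dwi(ph, sch, noise_sigma = ph$s0 / 15, seed = 1000 + s)
    matrix(dwi, nrow = V)[vx, 1]
  }, numeric(20))
  # per-voxel mean over 400 repeats: bias + sampling error both under 2%
  expect_lt(max(abs(rowMeans(sims) / ph$s0 - 1)), 0.02)
})

test_that("cohort generation produces the full session table deterministically", {
  spec <- cohort_spec(n_controls = 13L, n_pre_rt = 12L, n_post_rt = 38L,
                      phantom = phantom_spec(grid_shape = c(16L, 16L, 8L),
                                             tumor_radius = 6),
                      seed = 3L)
  d1 <- withr::local_tempdir()
  res <- make_longitudinal_cohort(spec, d1, write_dwi = FALSE)
  expect_equal(nrow(res$manifest), 63L)     # 50 patient scans + 13 controls
  expect_equal(sum(res$manifest$rt_status == "pre"), 12L)
  expect_equal(sum(res$manifest$rt_status == "post"), 38L)
  expect_true(all(res$manifest$delta_t_months[res$manifest$rt_status != "post"] == 0))
  # published layout: 18 patients with the published per-patient scan counts
  pat <- res$manifest[res$manifest$group == "patient", ]
  expect_equal(length(unique(pat$subject_id)), 18L)
  expect_equal(sort(as.integer(table(pat$subject_id))),
               sort(glioma_study_presets()$patients$scans))
  # seeded determinism: byte-identical ground-truth tables
  d2 <- withr::local_tempdir()
  res2 <- make_longitudinal_cohort(spec, d2, write_dwi = FALSE)
  expect_identical(res$ground_truth$true_delta_fa, res2$ground_truth$true_delta_fa)
  expect_identical(readLines(file.path(d1, "ground_truth.json"))[1],
                   readLines(file.path(d2, "ground_truth.json"))[1])
  # calibration: noiseless truth equals the drawn target (uniform-FA white
  # matter makes the blending inversion exact)
  expect_lt(max(abs(res$ground_truth$true_delta_fa -
                    res$ground_truth$target_delta_fa)), 1e-9)
})

test_that("NIfTI and gradient-table round trips preserve content", {
  a <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(a, p, voxel_size = c(2, 2, 2.8))
  r <- read_nifti(p)
  expect_equal(r$data, a, tolerance = 1e-6)           # float32 storage
  expect_equal(r$voxel_size, c(2, 2, 2.8), tolerance = 1e-6)

  sch <- make_gradient_scheme(12, 800, 2)
  bval <- withr::local_tempfile(fileext = ".bval")
  bvec <- withr::local_tempfile(fileext = ".bvec")
  write_gradient_table(sch, bval, bvec)
  sch2 <- read_gradient_table(bval, bvec)
  expect_equal(sch2$bvalues, sch$bvalues)
  expect_equal(sch2$directions, sch$directions, tolerance = 1e-9)
  expect_equal(length(readLines(bvec)), 3L)
})
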