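test_that("center of mass is the unweighted coordinate mean", {
  m <- array(FALSE, dim = c(20, 20, 10))
  m[11, 13, 6] <- TRUE                      # 0-based (10, 12, 5)
  expect_equal(center_of_mass(m), c(10, 12, 5))
  m <- array(FALSE, dim = c(5, 3, 3)); m[1, 1, 1] <- TRUE; m[3, 1, 1] <- TRUE
  expect_equal(center_of_mass(m), c(1, 0, 0))
  m <- array(FALSE, dim = c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
  expect_equal(center_of_mass(m), c(0.5, 0.5, 0.5))
  expect_error(center_of_mass(array(FALSE, dim = c(2, 2, 2))), "empty")
})

test_that("hemisphere masks partition the brain symmetrically", {
  ph <- small_phantom()
  brain <- ph$tissue > 0L
  h <- hemisphere_masks(brain)
  expect_false(any(h$left & h$right))
  expect_lt(abs(sum(h$left) - sum(h$right)), 0.01 * sum(brain))
  # partition: left + right + midline column + background = full grid
  mid <- brain & !h$left & !h$right
  expect_equal(sum(h$left) + sum(h$right) + sum(mid) + sum(!brain),
               prod(dim(brain)))
  # odd grid: the plane's own column is excluded
  b2 <- array(TRUE, dim = c(5, 4, 4))
  h2 <- hemisphere_masks(b2)
  expect_equal(sum(h2$left), 2 * 16)
  expect_equal(sum(h2$right), 2 * 16)
  expect_false(any(h2$left[3, , ] | h2$right[3, , ]))
  expect_error(hemisphere_masks(b2, midsagittal_x = 9), "outside")
})

test_that("thresholded mean averages only surviving voxels", {
  a <- array(0, dim = c(3, 1, 1)); a[] <- c(0.1, 0.3, 0.5)
  region <- array(TRUE, dim = dim(a))
  r <- thresholded_mean(a, region, a, 0.2)
  expect_equal(r$mean, 0.4)
  expect_equal(r$n_voxels, 2L)
  expect_true(r$valid)
  # all below threshold: invalid, not a crash
  r2 <- thresholded_mean(a * 0.1, region, a * 0.1, 0.2)
  expect_false(r2$valid)
  expect_equal(r2$n_voxels, 0L)
  # tumor overlap flags invalidity
  tm <- array(FALSE, dim = dim(a)); tm[3, 1, 1] <- TRUE
  r3 <- thresholded_mean(a, region, a, 0.2, tumor_mask = tm)
  expect_false(r3$valid)
  expect_equal(r3$tumor_overlap, 1L)
})

test_that("surviving voxel count is non-increasing in the FA threshold", {
  ph <- small_phantom(tumor = "right", f = 0.1)
  fa <- ph$true_fa
  region <- ph$hemispheres$right
  counts <- vapply(seq(0, 0.9, by = 0.1),
                   function(th) thresholded_mean(fa, region, fa, th)$n_voxels,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("local deltas behave on symmetric and tumor phantoms", {
  # symmetric noiseless phantom, no tumor: local delta 0 at every radius
  ph <- small_phantom()
  fa <- scalar_map(ph$true_fa, "FA", ph$voxel_size)
  roi <- roi_spec(radii = c(6, 10, 14), center = c(4.5, 7.5, 3.5))
  ld <- local_deltas(fa, roi, ph$hemispheres, "left")
  expect_true(all(abs(ld$delta_fa[ld$valid]) < 1e-10))
  # with a tumor: tiny radius fully inside the tumor is invalid
  pht <- small_phantom(tumor = "right", f = 0.1, radius = 6)
  fat <- scalar_map(pht$true_fa, "FA", pht$voxel_size)
  ctr <- center_of_mass(pht$tumor_mask)
  ld2 <- local_deltas(fat, roi_spec(radii = c(2, 20, 40), center = ctr),
                      pht$hemispheres, "right", tumor_mask = pht$tumor_mask)
  expect_false(ld2$valid[1])
  expect_true(all(ld2$valid[2:3]))
  expect_true(all(ld2$delta_fa[2:3] > 0))   # contralateral minus ipsilateral
  # large radius: agrees with the brute-force voxel loop restricted to spheres
  r <- 40
  sp <- hemidti:::sphere_mask(dim(fat$data), ctr, r, pht$voxel_size)
  mirror <- ctr; mirror[1] <- 2 * pht$midsagittal_x - ctr[1]
  ms <- hemidti:::sphere_mask(dim(fat$data), mirror, r, pht$voxel_size)
  ip <- fat$data[sp & pht$hemispheres$right & fat$data > 0.2]
  co <- fat$data[ms & pht$hemispheres$left & fat$data > 0.2]
  expect_equal(ld2$delta_fa[3], mean(co) - mean(ip), tolerance = 1e-10)
})

test_that("local deltas converge to the hemisphere-wide value at large radius", {
  pht <- small_phantom(tumor = "right", f = 0.1, radius = 6)
  fat <- scalar_map(pht$true_fa, "FA", pht$voxel_size)
  ctr <- center_of_mass(pht$tumor_mask)
  big <- 1000
  ld <- local_deltas(fat, roi_spec(radii = c(30, big), center = ctr),
                     pht$hemispheres, "right")
  # at an enormous radius both spheres cover their full hemispheres, but the
  # contralateral sphere is centered at the mirrored point: compare against
  # the hemisphere-restricted global value
  gd <- global_delta(list(FA = fat), pht$hemispheres, "right")
  expect_equal(ld$delta_fa[2], unname(gd$delta["delta_FA"]), tolerance = 1e-10)
})

test_that("global delta equals the generator's ground truth on noiseless phantoms", {
  ph <- small_phantom(tumor = "left", f = 0.05)
  maps <- list(FA = scalar_map(ph$true_fa, "FA", ph$voxel_size))
  gd <- global_delta(maps, ph$hemispheres, "left", tumor_mask = ph$tumor_mask)
  expect_equal(unname(gd$delta["delta_FA"]), ph$true_global_delta_fa,
               tolerance = 1e-6)
  expect_true(gd$valid)
  expect_error(global_delta(maps, ph$hemispheres, "up"), "invalid hemisphere")
})

test_that("mirroring the FA volume negates the global delta", {
  ph <- small_phantom(tumor = "right", f = 0.1)
  fa <- ph$true_fa
  flipped <- fa[rev(seq_len(dim(fa)[1])), , ]
  hemis <- ph$hemispheres
  hemis_f <- list(left = hemis$right[rev(seq_len(dim(fa)[1])), , ],
                  right = hemis$left[rev(seq_len(dim(fa)[1])), , ])
  gd <- global_delta(list(FA = scalar_map(fa, "FA", ph$voxel_size)), hemis, "right")
  gd_f <- global_delta(list(FA = scalar_map(flipped, "FA", ph$voxel_size)),
                       hemis_f, "left")
  expect_equal(unname(gd$delta["delta_FA"]), unname(gd_f$delta["delta_FA"]),
               tolerance = 1e-12)
  # flipping while keeping the tumor label on the same side negates the sign
  gd_neg <- global_delta(list(FA = scalar_map(flipped, "FA", ph$voxel_size)),
                         hemis_f, "right")
  expect_equal(unname(gd_neg$delta["delta_FA"]),
               -unname(gd$delta["delta_FA"]), tolerance = 1e-12)
})

test_that("all four metrics are thresholded on the FA map", {
  ph <- small_phantom(tumor = "right", f = 0.1)
  dwi <- simulate_dwi(ph, small_scheme(), noise_sigma = 0)
  res <- dwi_to_maps(dwi, small_scheme(), voxel_size = ph$voxel_size,
                     mask = ph$tissue > 0)
  hem <- ph$hemispheres
  gd <- global_delta(res$maps, hem, "right", tumor_mask = ph$tumor_mask)
  expect_named(gd$delta, c("delta_FA", "delta_MD", "delta_AD", "delta_RD"))
  # blending preserves MD exactly, so delta-MD ~ 0 while delta-FA > 0
  expect_gt(gd$delta["delta_FA"], 0.01)
  expect_lt(abs(gd$delta["delta_MD"]), 1e-8)
})
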