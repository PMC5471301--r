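# Analytic registration fixture: a smooth, textured, band-limited blob whose
# moved versions are sampled from the continuous function (no double
# interpolation), so recovery errors reflect the registration itself.
reg_fixture <- function(dm = c(24L, 24L, 12L), vs = c(2, 2, 2.8)) {
  f <- function(p) {
    ctr <- (dm - 1) / 2 * vs
    e <- ((p[, 1] - ctr[1]) / (0.4 * dm[1] * vs[1]))^2 +
         ((p[, 2] - ctr[2]) / (0.4 * dm[2] * vs[2]))^2 +
         ((p[, 3] - ctr[3]) / (0.4 * dm[3] * vs[3]))^2
    env <- pmax(0, 1 - e / 1.3)^2
    v <- env * (1 + 0.4 * sin(p[, 1] / 8) * cos(p[, 2] / 10) +
                0.3 * cos(p[, 1] / 12 + p[, 3] / 9))
    100 * pmax(v, 0)
  }
  g <- hemidti:::voxel_grid(dm)
  mm <- sweep(cbind(as.vector(g$x), as.vector(g$y), as.vector(g$z)), 2L, vs, `*`)
  fixed <- array(f(mm), dim = dm)
  moved_by <- function(t) {
    Mi <- transform_matrix(invert_transform(t))
    array(f(mm %*% t(Mi[1:3, 1:3]) +
            matrix(Mi[1:3, 4], nrow(mm), 3, byrow = TRUE)), dim = dm)
  }
  list(fixed = fixed, moved_by = moved_by, vs = vs, dm = dm)
}

resid_of <- function(t_hat, t_true) {
  rec <- compose_transform(t_hat, t_true)
  list(angle_deg = hemidti:::matrix_to_axis_angle(
         transform_matrix(rec)[1:3, 1:3])$angle * 180 / pi,
       trans_mm = max(abs(rec$translation)))
}

test_that("transform algebra: inverse, composition, serialization", {
  t <- rigid_transform(c(0.1, -0.05, 0.2), c(3, -2, 1), center = c(10, 12, 8))
  id <- compose_transform(t, invert_transform(t))
  expect_lt(max(abs(transform_matrix(id) - diag(4))), 1e-9)
  p <- withr::local_tempfile(fileext = ".json")
  write_transform_json(t, p)
  t2 <- read_transform_json(p)
  expect_equal(transform_matrix(t), transform_matrix(t2), tolerance = 1e-12)
})

test_that("halfway split composes exactly and halves pure motions", {
  # identity
  h <- halfway_split(rigid_transform())
  expect_lt(max(abs(transform_matrix(h$forward) - diag(4))), 1e-12)
  # pure translation: halves of +t/2 and -t/2
  t <- rigid_transform(translation = c(4, 0, 0))
  h <- halfway_split(t)
  expect_equal(h$forward$translation, c(2, 0, 0), tolerance = 1e-12)
  expect_equal(h$backward$translation, c(-2, 0, 0), tolerance = 1e-12)
  # 10 degree rotation: halves of 5 degrees, composition error < 1e-6
  t <- rigid_transform(angles = c(0, 0, 10 * pi / 180), translation = c(2, 1, 0))
  h <- halfway_split(t)
  expect_equal(h$forward$angles[3], 5 * pi / 180, tolerance = 1e-9)
  comp <- compose_transform(h$forward, h$forward)
  expect_lt(max(abs(transform_matrix(comp) - transform_matrix(t))), 1e-6)
  # backward is the inverse of forward
  expect_lt(max(abs(transform_matrix(compose_transform(h$forward, h$backward)) -
                    diag(4))), 1e-9)
  # general three-axis case still composes exactly
  t <- rigid_transform(angles = c(0.12, -0.2, 0.3), translation = c(5, -3, 2))
  h <- halfway_split(t)
  expect_lt(max(abs(transform_matrix(compose_transform(h$forward, h$forward)) -
                    transform_matrix(t))), 1e-9)
})

test_that("resampling round trip differs by interpolation error only", {
  fx <- reg_fixture()
  t <- rigid_transform(c(0.03, 0, 0.05), c(1.5, -1, 0.5))
  back <- resample_volume(resample_volume(fx$fixed, t, fx$vs),
                          invert_transform(t), fx$vs)
  core <- fx$fixed > 0.2 * max(fx$fixed)
  # two trilinear passes on a textured blob: relative MSE stays below 0.5%
  expect_lt(mean((back[core] - fx$fixed[core])^2) / mean(fx$fixed[core]^2), 5e-3)
})

test_that("registration recovers identity and injected perturbations", {
  fx <- reg_fixture()
  set.seed(1)
  # moving == fixed: parameters at identity
  t0 <- register_rigid(fx$fixed, fx$fixed, fx$vs, n_restarts = 0L)
  expect_lt(max(abs(t0$translation / fx$vs)), 0.01)         # < 0.01 voxel
  expect_lt(max(abs(t0$angles)) * 180 / pi, 0.1)            # < 0.1 degree
  # known 2-voxel translation
  t_tr <- rigid_transform(translation = c(2 * fx$vs[1], 0, 0))
  t_hat <- register_rigid(fx$moved_by(t_tr), fx$fixed, fx$vs, n_restarts = 1L)
  r <- resid_of(t_hat, t_tr)
  expect_lt(r$trans_mm / min(fx$vs), 0.1)                   # < 0.1 voxel
  # known 5 degree rotation
  t_rot <- rigid_transform(angles = c(0, 0, 5 * pi / 180),
                           center = center_of_mass(fx$fixed > 0) * fx$vs)
  t_hat <- register_rigid(fx$moved_by(t_rot), fx$fixed, fx$vs, n_restarts = 1L)
  r <- resid_of(t_hat, t_rot)
  expect_lt(r$angle_deg, 0.5)
  # best cost is non-increasing across restarts
  expect_true(all(diff(attr(t_hat, "cost_trace")) <= 1e-15))
})

test_that("b0 template construction aligns sessions into a common space", {
  fx <- reg_fixture()
  vs <- fx$vs
  set.seed(2)
  # identical sessions: template equals input, transforms near identity
  tpl <- build_b0_template(list(fx$fixed, fx$fixed), vs, n_restarts = 0L)
  expect_equal(tpl$template, fx$fixed, tolerance = 1e-6)
  for (tr in tpl$transforms) expect_lt(max(abs(tr$translation / vs)), 0.05)
  # two sessions offset by a known rigid perturbation end up in one space
  t_true <- rigid_transform(translation = c(3, 1, 0),
                            angles = c(0, 0, 2 * pi / 180),
                            center = center_of_mass(fx$fixed > 0) * vs)
  moved <- fx$moved_by(t_true)
  tpl <- build_b0_template(list(fx$fixed, moved), vs, n_restarts = 1L)
  a1 <- resample_volume(fx$fixed, tpl$transforms[[1]], vs)
  a2 <- resample_volume(moved, tpl$transforms[[2]], vs)
  core <- tpl$template > 0.3 * max(tpl$template)
  expect_lt(sqrt(mean((a1[core] - a2[core])^2)) / mean(fx$fixed[core]), 0.05)
  # the template is the voxelwise mean of the (halfway-)aligned inputs
  expect_equal(mean(tpl$template[core]),
               mean((a1[core] + a2[core]) / 2), tolerance = 0.05)
  # single session: identity with a warning record
  one <- build_b0_template(list(fx$fixed), vs)
  expect_match(one$warnings, "single session")
  expect_lt(max(abs(transform_matrix(one$transforms[[1]]) - diag(4))), 1e-12)
})

test_that("AC-PC alignment restores a rotated volume", {
  ph <- small_phantom()
  vs <- ph$voxel_size
  img <- array(0, dim = ph$grid_shape)
  img[ph$tissue > 0] <- 100
  g <- hemidti:::voxel_grid(ph$grid_shape)
  img <- img * (1 + 0.2 * sin(g$y / 2))
  # already aligned: identity within tolerance
  al <- acpc_align(img, ph$acpc$ac, ph$acpc$pc, vs)
  expect_lt(max(abs(transform_matrix(al$transform) - diag(4))), 1e-9)
  # rotate by 8 degrees in-plane, move landmarks accordingly, re-align
  ang <- 8 * pi / 180
  ctr_mm <- ((ph$grid_shape - 1) / 2) * vs
  t_rot <- rigid_transform(angles = c(0, 0, ang), center = ctr_mm)
  rot_img <- resample_volume(img, t_rot, vs)
  rot_pt <- function(p) hemidti:::transform_points(t_rot, matrix(p, 1), vs)[1, ]
  ac_r <- rot_pt(ph$acpc$ac); pc_r <- rot_pt(ph$acpc$pc)
  al2 <- acpc_align(rot_img, ac_r, pc_r, vs, ac_reference = ph$acpc$ac)
  # the AC-PC axis must be restored to the +y grid axis within 0.5 degree
  d <- (ac_r - pc_r) * vs
  d_new <- transform_matrix(al2$transform)[1:3, 1:3] %*% d
  ang_off <- acos(min(1, sum(d_new * c(0, 1, 0)) / sqrt(sum(d_new^2))))
  expect_lt(ang_off * 180 / pi, 0.5)
  # 4D contract: every sub-volume receives the same transform
  vol4 <- array(c(img, img * 2), dim = c(ph$grid_shape, 2))
  al4 <- acpc_align(vol4, ph$acpc$ac, ph$acpc$pc, vs)
  expect_equal(al4$volume[, , , 2], 2 * al4$volume[, , , 1], tolerance = 1e-9)
  expect_error(acpc_align(img, c(1, 1, 1), c(1, 1, 1), vs), "coincide")
})
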