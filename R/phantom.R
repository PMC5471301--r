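# Digital DTI phantom with known ground truth: an ellipsoidal "brain" of
# coherent white matter, an optional isotropic tumor sphere (FA < 0.2), and an
# optional hemisphere-wide anisotropy reduction emulating post-radiation
# white-matter damage.

#' Specify a DTI phantom
#'
#' The default geometry is a desk-scale version of a clinical acquisition:
#' 48 x 48 x 24 voxels at 2.0 x 2.0 x 2.8 mm (the full 128 x 128 x 64 matrix
#' is available by argument). White matter carries a single-fiber tensor with
#' eigenvalues `wm_eigenvalues` whose principal axis varies smoothly across
#' the volume; tumor voxels are isotropic (ground-truth FA = 0, below the 0.2
#' white-matter threshold); in the reduction hemisphere the tensor is blended
#' linearly toward its isotropic part by `fa_reduction_factor`, which lowers
#' FA monotonically while keeping MD constant.
#'
#' @param grid_shape integer length-3, voxels per axis (x = left-right).
#' @param voxel_size numeric length-3, mm.
#' @param wm_eigenvalues descending tensor eigenvalues in mm2/s.
#' @param tumor_hemisphere `"left"`, `"right"` or `"none"` (control).
#' @param tumor_center voxel coordinates (0-based, real-valued) or `NULL` for
#'   a default location centered in the tumor hemisphere.
#' @param tumor_radius tumor sphere radius in mm.
#' @param fa_reduction_factor blending factor in `[0, 1]` toward isotropy.
#' @param reduction_hemisphere hemisphere whose white matter is blended;
#'   defaults to the tumor hemisphere (ipsilateral damage). For control
#'   phantoms with a nonzero factor it must be given explicitly.
#' @param noise_sigma default acquisition noise (signal units) used by
#'   [simulate_dwi()]; the default gives SNR 20 at b0.
#' @param s0 baseline (b = 0) signal.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 24L),
                         voxel_size = c(2, 2, 2.8),
                         wm_eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                         tumor_hemisphere = c("none", "left", "right"),
                         tumor_center = NULL,
                         tumor_radius = 12,
                         fa_reduction_factor = 0,
                         reduction_hemisphere = NULL,
                         noise_sigma = 5,
                         s0 = 100) {
  tumor_hemisphere <- match.arg(tumor_hemisphere)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            all(grid_shape >= 8L), all(voxel_size > 0))
  if (tumor_radius <= 0) stop("tumor_radius must be positive")
  if (fa_reduction_factor < 0 || fa_reduction_factor > 1)
    stop("fa_reduction_factor must be in [0, 1]")
  if (any(wm_eigenvalues <= 0) || is.unsorted(rev(wm_eigenvalues)))
    stop("wm_eigenvalues must be positive and sorted descending")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (is.null(reduction_hemisphere)) {
    reduction_hemisphere <- if (tumor_hemisphere == "none") "none" else tumor_hemisphere
  }
  if (reduction_hemisphere == "none" && fa_reduction_factor > 0)
    stop("fa_reduction_factor > 0 requires a reduction hemisphere")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 wm_eigenvalues = as.numeric(wm_eigenvalues),
                 tumor_hemisphere = tumor_hemisphere,
                 tumor_center = tumor_center,
                 tumor_radius = tumor_radius,
                 fa_reduction_factor = fa_reduction_factor,
                 reduction_hemisphere = reduction_hemisphere,
                 noise_sigma = noise_sigma,
                 s0 = s0),
            class = "phantom_spec")
}

# 0-based voxel coordinate grids for a volume shape.
voxel_grid <- function(dm) {
  list(x = array(rep(seq_len(dm[1]) - 1, times = dm[2] * dm[3]), dim = dm),
       y = array(rep(rep(seq_len(dm[2]) - 1, each = dm[1]), times = dm[3]), dim = dm),
       z = array(rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]), dim = dm))
}

#' Build a phantom with ground truth
#'
#' Realizes a [phantom_spec()] into a per-voxel tensor field, tissue labels
#' (`0` background, `1` white matter, `2` tumor), hemisphere masks split at
#' the midsagittal plane, and the noiseless ground-truth global
#' interhemispheric FA difference computed from the tensors themselves
#' (healthy-hemisphere mean minus tumor-hemisphere mean over voxels with
#' ground-truth FA above `fa_threshold`; left minus right for controls).
#'
#' @param spec a `phantom_spec`.
#' @param fa_threshold white-matter FA threshold used for the ground-truth
#'   delta (default 0.2).
#' @return object of class `dti_phantom`: `tensor` (V x 6 matrix, columns
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `tissue` (3D integer array),
#'   `hemispheres` (list of logical arrays `left`, `right`), `tumor_mask`,
#'   `true_global_delta_fa`, `midsagittal_x`, `acpc` landmark list, plus the
#'   spec fields.
#' @export
build_phantom <- function(spec, fa_threshold = 0.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  ctr <- (dm - 1) / 2                      # 0-based grid center
  g <- voxel_grid(dm)
  semi <- 0.85 * vs * dm / 2               # brain ellipsoid semi-axes, mm
  e <- ((g$x - ctr[1]) * vs[1] / semi[1])^2 +
       ((g$y - ctr[2]) * vs[2] / semi[2])^2 +
       ((g$z - ctr[3]) * vs[3] / semi[3])^2
  brain <- e <= 1
  tissue <- array(0L, dim = dm)
  tissue[brain] <- 1L

  mid_x <- ctr[1]
  tumor_mask <- array(FALSE, dim = dm)
  if (spec$tumor_hemisphere != "none") {
    tc <- spec$tumor_center
    if (is.null(tc)) {
      off <- (semi[1] / vs[1]) / 2         # halfway out along x
      tc <- c(if (spec$tumor_hemisphere == "left") mid_x - off else mid_x + off,
              ctr[2], ctr[3])
    }
    # the sphere must stay strictly inside its hemisphere
    gap_mm <- (abs(tc[1] - mid_x)) * vs[1]
    if (gap_mm <= spec$tumor_radius)
      stop("tumor sphere overlaps the midsagittal plane ",
           "(center-to-midline distance ", signif(gap_mm, 4), " mm <= radius ",
           spec$tumor_radius, " mm)")
    on_side <- if (spec$tumor_hemisphere == "left") tc[1] < mid_x else tc[1] > mid_x
    if (!on_side) stop("tumor_center is not in the stated hemisphere")
    d2 <- ((g$x - tc[1]) * vs[1])^2 + ((g$y - tc[2]) * vs[2])^2 +
          ((g$z - tc[3]) * vs[3])^2
    tumor_mask <- brain & d2 <= spec$tumor_radius^2
    tissue[tumor_mask] <- 2L
  }

  # smoothly varying principal fiber direction in the x-y plane
  vx <- which(tissue > 0L)
  phi <- 0.6 * sin(2 * pi * g$z[vx] / dm[3]) + 0.4 * pi * (g$x[vx] / dm[1] - 0.5)
  dvec <- cbind(sin(phi), cos(phi), 0.2 * cos(2 * pi * g$y[vx] / dm[2]))
  dvec <- dvec / sqrt(rowSums(dvec^2))
  # orthonormal complement (u in the horizontal plane, v = d x u)
  u <- cbind(dvec[, 2], -dvec[, 1], 0)
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dvec[, 2] * u[, 3] - dvec[, 3] * u[, 2],
             dvec[, 3] * u[, 1] - dvec[, 1] * u[, 3],
             dvec[, 1] * u[, 2] - dvec[, 2] * u[, 1])
  lam <- spec$wm_eigenvalues
  md <- mean(lam)
  outer6 <- function(a) cbind(a[, 1]^2, a[, 2]^2, a[, 3]^2,
                              a[, 1] * a[, 2], a[, 1] * a[, 3], a[, 2] * a[, 3])
  D <- lam[1] * outer6(dvec) + lam[2] * outer6(u) + lam[3] * outer6(v)

  # tumor: isotropic at white-matter MD (ground-truth FA = 0 < 0.2)
  tum <- tissue[vx] == 2L
  D[tum, ] <- rep(c(md, md, md, 0, 0, 0), each = sum(tum))

  # hemisphere-wide blending toward isotropy (FA reduction, MD preserved)
  f <- spec$fa_reduction_factor
  if (f > 0) {
    xs <- g$x[vx]
    in_red <- if (spec$reduction_hemisphere == "left") xs < mid_x else xs > mid_x
    in_red <- in_red & !tum
    mdv <- (D[in_red, 1] + D[in_red, 2] + D[in_red, 3]) / 3
    iso <- cbind(mdv, mdv, mdv, 0, 0, 0)
    D[in_red, ] <- (1 - f) * D[in_red, , drop = FALSE] + f * iso
  }

  tensor <- matrix(0, nrow = prod(dm), ncol = 6L)
  tensor[vx, ] <- D

  hemis <- hemisphere_masks(tissue > 0L, midsagittal_x = mid_x)
  ev <- eigvals_sym3(tensor[vx, , drop = FALSE])
  fa <- array(0, dim = dm)
  fa[vx] <- fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
  tgt <- phantom_truth_delta(fa, hemis, spec$tumor_hemisphere, fa_threshold)

  acpc <- list(ac = c(mid_x, ctr[2] + 5, ctr[3]),
               pc = c(mid_x, ctr[2] - 5, ctr[3]))
  structure(c(list(tensor = tensor, tissue = tissue, hemispheres = hemis,
                   tumor_mask = tumor_mask, true_fa = fa,
                   true_global_delta_fa = tgt, midsagittal_x = mid_x,
                   acpc = acpc, fa_threshold = fa_threshold),
              unclass(spec)),
            class = "dti_phantom")
}

# Ground-truth global delta from a noiseless FA array.
phantom_truth_delta <- function(fa, hemis, tumor_hemisphere, fa_threshold) {
  m <- function(h) mean(fa[h & fa > fa_threshold])
  if (tumor_hemisphere == "right") m(hemis$left) - m(hemis$right)
  else if (tumor_hemisphere == "left") m(hemis$right) - m(hemis$left)
  else m(hemis$left) - m(hemis$right)    # control convention: left - right
}

#' FA of a blended single-fiber tensor
#'
#' Analytic FA after linear blending of a tensor with eigenvalues `lambda`
#' toward its isotropic part by factor `f`: the blended eigenvalues are
#' `(1 - f) * lambda + f * mean(lambda)`.
#'
#' @param f blending factor(s) in `[0, 1]`.
#' @param lambda descending eigenvalues (mm2/s).
#' @return FA value(s).
#' @export
blended_fa <- function(f, lambda) {
  md <- mean(lambda)
  l <- outer(1 - f, lambda) + f * md
  fa_from_eigenvalues(l[, 1], l[, 2], l[, 3])
}

#' Calibrate the FA-reduction factor to a target delta-FA
#'
#' Inverts the blending model: finds `f` such that the noiseless global
#' interhemispheric FA difference of a phantom with uniform white-matter
#' eigenvalues `lambda` equals `|target_delta|` (the affected hemisphere's FA
#' is `blended_fa(f, lambda)`, the other hemisphere's is `blended_fa(0,
#' lambda)`). Negative targets are realized by blending the contralateral
#' (healthy) hemisphere instead; the returned `hemisphere_sign` records this.
#'
#' @param target_delta desired signed global delta-FA.
#' @param lambda white-matter eigenvalues.
#' @return list with `factor` in `[0, 1]` and `hemisphere_sign` (+1: reduce
#'   the tumor/ipsilateral hemisphere, -1: reduce the contralateral one).
#' @export
calibrate_fa_reduction <- function(target_delta, lambda = c(1.7e-3, 0.3e-3, 0.3e-3)) {
  fa0 <- blended_fa(0, lambda)
  amag <- abs(target_delta)
  if (amag >= fa0)
    stop("target |delta-FA| ", amag, " exceeds the phantom's baseline FA ", signif(fa0, 4))
  if (amag == 0) return(list(factor = 0, hemisphere_sign = 1))
  f <- stats::uniroot(function(f) (fa0 - blended_fa(f, lambda)) - amag,
                      c(0, 1), tol = 1e-12)$root
  list(factor = f, hemisphere_sign = if (target_delta >= 0) 1 else -1)
}

#' @export
print.dti_phantom <- function(x, ...) {
  cat(sprintf(paste0("<dti_phantom> %s voxels at %s mm; tumor: %s; ",
                     "fa_reduction %.4g (%s); true delta-FA = %.5f\n"),
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              x$tumor_hemisphere, x$fa_reduction_factor,
              x$reduction_hemisphere, x$true_global_delta_fa))
  invisible(x)
}
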