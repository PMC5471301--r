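# Intensity-based rigid registration, halfway template construction, and
# AC-PC standardization.

# masked mean squared difference after per-image median normalization
registration_cost <- function(par, moving, fixed, mask_idx, center, voxel_size,
                              fixed_norm) {
  t <- rigid_transform(par[1:3], par[4:6], center)
  res <- resample_volume(moving, t, voxel_size)
  mv <- res[mask_idx]
  med <- stats::median(mv[mv > 0])
  if (!is.finite(med) || med <= 0) return(NA_real_)
  mean((mv / med - fixed_norm)^2)
}

#' Rigid registration of two images
#'
#' Estimates the 6-parameter rigid transform mapping `moving` onto `fixed`
#' by minimizing the mean squared intensity difference over the fixed
#' image's brain mask (both images scaled by their masked median, making the
#' cost insensitive to global intensity). Optimization is derivative-free
#' Nelder-Mead simplex descent with `n_restarts` additional starts from
#' perturbed initializations; a restart is accepted only if it lowers the
#' cost, so the best cost is non-increasing across restarts. The rotation
#' center is the center of mass of the fixed mask. Resampling is trilinear.
#'
#' @param moving,fixed 3D arrays on the same grid and voxel size.
#' @param voxel_size mm.
#' @param init optional initial `rigid_transform`.
#' @param mask optional fixed-image mask; defaults to [brain_mask()] of
#'   `fixed`.
#' @param n_restarts perturbed restarts after the initial optimization
#'   (default 3).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a `rigid_transform` with attributes `cost` (final cost) and
#'   `cost_trace` (best cost after the initial run and each restart).
#' @export
register_rigid <- function(moving, fixed, voxel_size = c(1, 1, 1), init = NULL,
                           mask = NULL, n_restarts = 3L, maxit = 800L) {
  stopifnot(identical(dim(moving), dim(fixed)))
  if (is.null(mask)) mask <- brain_mask(fixed)
  mask_idx <- which(mask)
  if (length(mask_idx) == 0L) stop("empty registration mask")
  center <- center_of_mass(mask) * voxel_size
  fx <- fixed[mask_idx]
  med <- stats::median(fx[fx > 0])
  if (!is.finite(med) || med <= 0) stop("non-finite registration cost: empty overlap")
  fixed_norm <- fx / med
  p0 <- if (is.null(init)) rep(0, 6) else c(init$angles, init$translation)
  cost_fn <- function(p) {
    v <- registration_cost(p, moving, fixed, mask_idx, center, voxel_size, fixed_norm)
    if (!is.finite(v)) 1e6 else v
  }
  fit <- stats::optim(p0, cost_fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12,
                                     parscale = c(rep(0.05, 3), rep(2, 3))))
  best <- fit
  trace <- fit$value
  if (n_restarts > 0L) {
    for (k in seq_len(n_restarts)) {
      pert <- best$par + c(stats::runif(3, -0.02, 0.02), stats::runif(3, -1, 1))
      cand <- stats::optim(pert, cost_fn, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = 1e-12,
                                     parscale = c(rep(0.05, 3), rep(2, 3))))
      if (cand$value < best$value) best <- cand
      trace <- c(trace, best$value)
    }
  }
  out <- rigid_transform(best$par[1:3], best$par[4:6], center)
  attr(out, "cost") <- best$value
  attr(out, "cost_trace") <- trace
  out
}

#' Per-subject b0 template construction
#'
#' Reproduces the two-step longitudinal alignment: (1) every follow-up b0 is
#' registered to the baseline (first session) and moved halfway toward it;
#' (2) the voxelwise mean of the baseline and the halfway-moved follow-ups
#' forms the subject's b0 template; (3) every original b0 map, including the
#' baseline, is registered to that template, minimizing the bias toward the
#' baseline scan. With a single session the identity transform is returned
#' with a warning record.
#'
#' @param b0_list list of 3D arrays (session b0 maps), baseline first.
#' @param voxel_size mm.
#' @param halfway `"symmetric"` (default; follow-ups move half the estimated
#'   transform before averaging) or `"moving-only"` (follow-ups move fully).
#' @param ... passed to [register_rigid()].
#' @return object of class `template_result`: `template` (3D array),
#'   `transforms` (list of final per-session `rigid_transform`s into
#'   template space), `final_costs`, `warnings`.
#' @export
build_b0_template <- function(b0_list, voxel_size = c(1, 1, 1),
                              halfway = c("symmetric", "moving-only"), ...) {
  halfway <- match.arg(halfway)
  n <- length(b0_list)
  if (n == 0L) stop("no sessions")
  if (n == 1L) {
    return(structure(list(template = b0_list[[1L]],
                          transforms = list(rigid_transform()),
                          final_costs = NA_real_,
                          warnings = "single session: identity transform"),
                     class = "template_result"))
  }
  baseline <- b0_list[[1L]]
  aligned <- vector("list", n)
  aligned[[1L]] <- baseline
  for (i in 2:n) {
    t_full <- register_rigid(b0_list[[i]], baseline, voxel_size, ...)
    t_use <- if (halfway == "symmetric") halfway_split(t_full)$forward else t_full
    aligned[[i]] <- resample_volume(b0_list[[i]], t_use, voxel_size)
  }
  template <- Reduce(`+`, aligned) / n
  transforms <- vector("list", n)
  costs <- numeric(n)
  for (i in seq_len(n)) {
    tr <- register_rigid(b0_list[[i]], template, voxel_size, ...)
    transforms[[i]] <- tr
    costs[i] <- attr(tr, "cost")
  }
  structure(list(template = template, transforms = transforms,
                 final_costs = costs, warnings = character()),
            class = "template_result")
}

#' Rigid AC-PC standardization
#'
#' Rotates and translates the volume so the anterior commissure-posterior
#' commissure (AC-PC) segment lies along the anterior-posterior grid axis
#' within the midsagittal plane, with AC moved to a reference coordinate
#' (default: its projection onto the aligned grid). Landmarks come from
#' phantom metadata or a sidecar file; no automatic detection is attempted.
#' For 4D input the same transform is applied to every sub-volume.
#'
#' @param vol 3D or 4D array.
#' @param ac,pc landmark voxel coordinates (0-based, real-valued).
#' @param voxel_size mm.
#' @param ac_reference target voxel coordinate for AC after alignment;
#'   default keeps AC in place.
#' @return list with `volume` (resampled array) and `transform`
#'   (`rigid_transform`).
#' @export
acpc_align <- function(vol, ac, pc, voxel_size = c(1, 1, 1), ac_reference = ac) {
  if (sqrt(sum(((ac - pc) * voxel_size)^2)) < 1e-9)
    stop("AC and PC landmarks coincide")
  ac_mm <- ac * voxel_size
  pc_mm <- pc * voxel_size
  d <- ac_mm - pc_mm                      # PC -> AC should point anterior (+y)
  d <- d / sqrt(sum(d^2))
  target <- c(0, 1, 0)
  axis <- c(d[2] * target[3] - d[3] * target[2],
            d[3] * target[1] - d[1] * target[3],
            d[1] * target[2] - d[2] * target[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(d * target)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else axis_angle_to_matrix(c(0, 0, 1), pi)
  } else {
    axis_angle_to_matrix(axis / s, atan2(s, cth))
  }
  # rotate about AC, then translate AC to the reference
  trans <- ac_reference * voxel_size - ac_mm
  t <- rigid_transform(matrix_to_euler(R), trans, center = ac_mm)
  list(volume = resample_volume(vol, t, voxel_size), transform = t)
}
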