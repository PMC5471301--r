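# Local (tumor-centered ROI) and global (whole-hemisphere) interhemispheric
# differences of FA-thresholded metric averages.

#' Center of mass of a binary mask
#'
#' Unweighted mean of the 0-based voxel coordinates of the foreground.
#'
#' @param mask logical or 0/1 3D array.
#' @return numeric length-3 (real-valued voxel coordinates, 0-based).
#' @export
center_of_mass <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  vx <- which(mask != 0)
  if (length(vx) == 0L) stop("center_of_mass: empty mask")
  idx <- arrayInd(vx, dim(mask)) - 1L
  colMeans(idx)
}

#' Split a brain mask into hemispheres at the midsagittal plane
#'
#' The volume is assumed AC-PC aligned with the midsagittal plane
#' perpendicular to the first (left-right) axis at `midsagittal_x` (0-based,
#' may be half-integer for even grids). Voxels whose x index is within half a
#' voxel of the plane belong to neither hemisphere.
#'
#' @param brain_mask logical 3D array.
#' @param midsagittal_x 0-based plane position along dim 1; defaults to the
#'   grid center `(nx - 1) / 2`.
#' @return list of logical arrays `left` (x < plane) and `right` (x > plane).
#' @export
hemisphere_masks <- function(brain_mask, midsagittal_x = NULL) {
  stopifnot(is.array(brain_mask), length(dim(brain_mask)) == 3L)
  dm <- dim(brain_mask)
  if (is.null(midsagittal_x)) midsagittal_x <- (dm[1] - 1) / 2
  if (midsagittal_x < 0 || midsagittal_x > dm[1] - 1)
    stop("midsagittal plane outside the grid")
  x <- voxel_grid(dm)$x
  on_plane <- abs(x - midsagittal_x) < 0.5
  list(left = brain_mask & x < midsagittal_x & !on_plane,
       right = brain_mask & x > midsagittal_x & !on_plane)
}

#' FA-thresholded regional mean
#'
#' Mean of `map` over the voxels of `region` whose FA exceeds
#' `fa_threshold` (default 0.2, excluding gray matter and tumor tissue which
#' fall below it). For the FA metric itself, pass the same map twice. When a
#' tumor mask is supplied, a programmatic quality check verifies that no
#' surviving voxel lies inside the tumor (replacing a visual T2-based check);
#' an overlap marks the result invalid.
#'
#' @param map `scalar_map` or 3D array to average.
#' @param region logical 3D array.
#' @param fa_map `scalar_map` or 3D FA array used for thresholding.
#' @param fa_threshold FA cutoff (default 0.2).
#' @param tumor_mask optional logical array for the quality check.
#' @return list with `mean`, `n_voxels`, `valid`, and `tumor_overlap`.
#' @export
thresholded_mean <- function(map, region, fa_map, fa_threshold = 0.2,
                             tumor_mask = NULL) {
  a <- if (inherits(map, "scalar_map")) map$data else map
  fa <- if (inherits(fa_map, "scalar_map")) fa_map$data else fa_map
  stopifnot(identical(dim(a), dim(fa)), identical(dim(a), dim(region)))
  keep <- region & fa > fa_threshold
  n <- sum(keep)
  overlap <- if (is.null(tumor_mask)) 0L else sum(keep & tumor_mask)
  if (n == 0L)
    return(list(mean = NA_real_, n_voxels = 0L, valid = FALSE,
                tumor_overlap = overlap))
  list(mean = mean(a[keep]), n_voxels = n, valid = overlap == 0L,
       tumor_overlap = overlap)
}

# Spherical mask in mm around a (0-based) voxel-coordinate center.
sphere_mask <- function(dm, center, radius_mm, voxel_size) {
  g <- voxel_grid(dm)
  d2 <- ((g$x - center[1]) * voxel_size[1])^2 +
        ((g$y - center[2]) * voxel_size[2])^2 +
        ((g$z - center[3]) * voxel_size[3])^2
  d2 <= radius_mm^2
}

#' ROI specification for local interhemispheric differences
#'
#' @param radii strictly increasing sphere radii in mm (default 10 to 60 mm
#'   in 10 mm steps).
#' @param center 0-based voxel coordinates of the ROI center (typically the
#'   tumor center of mass), or `NULL` to derive it from a tumor mask.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(radii = seq(10, 60, by = 10), center = NULL) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing and positive")
  structure(list(radii = as.numeric(radii), center = center), class = "roi_spec")
}

#' Local interhemispheric FA differences around the tumor
#'
#' For each radius, a sphere around the tumor center of mass is clipped to
#' the tumor hemisphere; its mirror image (center reflected across the
#' midsagittal plane) is clipped to the contralateral hemisphere. The local
#' difference is the contralateral minus the ipsilateral FA-thresholded mean.
#' Radii whose ROI retains no voxel above the FA threshold (e.g. spheres
#' contained in the tumor) are flagged invalid.
#'
#' @param fa_map `scalar_map` of FA.
#' @param roi an [roi_spec()]; if its center is `NULL`, `tumor_mask` must be
#'   given and its [center_of_mass()] is used.
#' @param hemispheres list from [hemisphere_masks()].
#' @param tumor_hemisphere `"left"` or `"right"`.
#' @param midsagittal_x 0-based midsagittal plane position.
#' @param fa_threshold FA cutoff.
#' @param tumor_mask optional tumor mask (for the center and quality check).
#' @return data.frame with columns `radius_mm`, `delta_fa`, `n_ipsi`,
#'   `n_contra`, `valid`.
#' @export
local_deltas <- function(fa_map, roi, hemispheres, tumor_hemisphere,
                         midsagittal_x = NULL, fa_threshold = 0.2,
                         tumor_mask = NULL) {
  fa <- if (inherits(fa_map, "scalar_map")) fa_map$data else fa_map
  vs <- if (inherits(fa_map, "scalar_map")) fa_map$voxel_size else c(1, 1, 1)
  dm <- dim(fa)
  if (is.null(midsagittal_x)) midsagittal_x <- (dm[1] - 1) / 2
  center <- roi$center
  if (is.null(center)) {
    if (is.null(tumor_mask)) stop("need an ROI center or a tumor mask")
    center <- center_of_mass(tumor_mask)
  }
  ipsi <- hemispheres[[tumor_hemisphere]]
  contra <- hemispheres[[setdiff(c("left", "right"), tumor_hemisphere)]]
  mirror_center <- center
  mirror_center[1] <- 2 * midsagittal_x - center[1]
  rows <- lapply(roi$radii, function(r) {
    sp <- sphere_mask(dm, center, r, vs)
    ms <- sphere_mask(dm, mirror_center, r, vs)
    a <- thresholded_mean(fa, sp & ipsi, fa, fa_threshold, tumor_mask)
    b <- thresholded_mean(fa, ms & contra, fa, fa_threshold)
    data.frame(radius_mm = r,
               delta_fa = if (a$valid && b$valid) b$mean - a$mean else NA_real_,
               n_ipsi = a$n_voxels, n_contra = b$n_voxels,
               valid = a$valid && b$valid)
  })
  do.call(rbind, rows)
}

#' Global interhemispheric differences for all four DTI metrics
#'
#' The study's central statistic: for each metric (FA, MD, AD, RD), the
#' healthy-hemisphere FA-thresholded mean minus the tumor-hemisphere one.
#' Thresholding always uses the FA map, so all metrics average over the same
#' white-matter voxel set. For control sessions (`tumor_hemisphere =
#' "none"`), the signed convention left minus right is used.
#'
#' @param maps named list of `scalar_map`s containing at least `FA`.
#' @param hemispheres list from [hemisphere_masks()].
#' @param tumor_hemisphere `"left"`, `"right"` or `"none"`.
#' @param fa_threshold FA cutoff (default 0.2).
#' @param tumor_mask optional tumor mask for the quality check.
#' @param session_id identifier copied into the result.
#' @return object of class `delta_result`: list with `session_id`, `delta`
#'   (named numeric, one entry per metric), `n_healthy`, `n_tumor_side`,
#'   `fa_threshold`, `valid`, `hemispheres_used`.
#' @export
global_delta <- function(maps, hemispheres, tumor_hemisphere = "none",
                         fa_threshold = 0.2, tumor_mask = NULL,
                         session_id = NA_character_) {
  if (!tumor_hemisphere %in% c("left", "right", "none"))
    stop("invalid hemisphere label: ", tumor_hemisphere)
  if (!"FA" %in% names(maps)) stop("maps must contain an FA map")
  tumor_side <- if (tumor_hemisphere == "none") "right" else tumor_hemisphere
  healthy_side <- setdiff(c("left", "right"), tumor_side)
  fa <- maps$FA
  res <- lapply(maps, function(m) {
    h <- thresholded_mean(m, hemispheres[[healthy_side]], fa, fa_threshold)
    t <- thresholded_mean(m, hemispheres[[tumor_side]], fa, fa_threshold,
                          tumor_mask = tumor_mask)
    list(delta = h$mean - t$mean, n_h = h$n_voxels, n_t = t$n_voxels,
         valid = h$valid && t$valid)
  })
  delta <- vapply(res, `[[`, numeric(1), "delta")
  names(delta) <- paste0("delta_", names(maps))
  structure(list(session_id = session_id,
                 delta = delta,
                 n_healthy = res$FA$n_h,
                 n_tumor_side = res$FA$n_t,
                 fa_threshold = fa_threshold,
                 valid = all(vapply(res, `[[`, logical(1), "valid")) &&
                         res$FA$n_h > 0L && res$FA$n_t > 0L,
                 healthy_hemisphere = healthy_side,
                 tumor_hemisphere = tumor_hemisphere),
            class = "delta_result")
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("<delta_result %s> %s | n = %d / %d voxels%s\n",
              x$session_id,
              paste(sprintf("%s = %.5f", names(x$delta), x$delta), collapse = ", "),
              x$n_healthy, x$n_tumor_side,
              if (x$valid) "" else " [INVALID]"))
  invisible(x)
}
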