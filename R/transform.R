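# Rigid transforms: 3 rotation angles + 3 translations, applied as a
# rotation about a fixed center (mm) followed by a translation (mm).

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# intrinsic composition R = Rz(az) Ry(ay) Rx(ax)
euler_to_matrix <- function(angles) rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])

matrix_to_euler <- function(R) {
  ay <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ay)) > 1e-9) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {         # gimbal lock
    ax <- atan2(-R[2, 3], R[2, 2])
    az <- 0
  }
  c(ax, ay, az)
}

# rotation matrix <-> axis-angle (for the exact halfway square root)
matrix_to_axis_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ang <- acos(pmin(pmax(ca, -1), 1))
  if (ang < 1e-12) return(list(axis = c(1, 0, 0), angle = 0))
  if (abs(pi - ang) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    axis <- B[, k] / axis[k]
    return(list(axis = axis / sqrt(sum(axis^2)), angle = ang))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  list(axis = axis, angle = ang)
}

axis_angle_to_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Construct a rigid transform
#'
#' A 6-parameter rigid-body transform: rotation by Euler angles (radians,
#' intrinsic z-y-x order) about a fixed center point (mm), then translation
#' (mm): `y = R (x - c) + c + t`.
#'
#' @param angles rotation angles in radians, length 3.
#' @param translation translation in mm, length 3.
#' @param center rotation center in mm, length 3 (default the origin).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3L, length(translation) == 3L, length(center) == 3L)
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (deg): %s; translation (mm): %s\n",
              paste(sprintf("%.3f", x$angles * 180 / pi), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t a `rigid_transform`.
#' @return 4x4 numeric matrix acting on mm coordinates.
#' @export
transform_matrix <- function(t) {
  R <- euler_to_matrix(t$angles)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center - R %*% t$center + t$translation
  M
}

# rebuild a rigid_transform (with a given center) from a 4x4 matrix
transform_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  trans <- M[1:3, 4] - center + as.numeric(R %*% center)
  rigid_transform(matrix_to_euler(R), trans, center)
}

#' Compose two rigid transforms
#' @param t2,t1 `rigid_transform`s; the result applies `t1` first, then `t2`.
#' @return a `rigid_transform` (with `t1`'s center).
#' @export
compose_transform <- function(t2, t1) {
  transform_from_matrix(transform_matrix(t2) %*% transform_matrix(t1), t1$center)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return its inverse (same center).
#' @export
invert_transform <- function(t) {
  M <- transform_matrix(t)
  Mi <- diag(4)
  Mi[1:3, 1:3] <- t(M[1:3, 1:3])
  Mi[1:3, 4] <- -t(M[1:3, 1:3]) %*% M[1:3, 4]
  transform_from_matrix(Mi, t$center)
}

#' Split a rigid transform into symmetric halves
#'
#' Returns the exact "square root" of the transform and its inverse: the
#' forward half rotates by half the rotation angle about the same axis, with
#' the translation solved so that composing the forward half with itself
#' reproduces the original transform exactly; the backward half is the
#' forward half's inverse. Moving the first image by the forward half and
#' the second by the backward half places both at the geometric midpoint, so
#' the interpolation burden is shared symmetrically. For a pure translation
#' the halves are `+t/2` and `-t/2`.
#'
#' @param t a `rigid_transform`.
#' @return list with `forward` and `backward` `rigid_transform`s.
#' @export
halfway_split <- function(t) {
  R <- euler_to_matrix(t$angles)
  aa <- matrix_to_axis_angle(R)
  Rh <- axis_angle_to_matrix(aa$axis, aa$angle / 2)
  # T = Th o Th  =>  (Rh + I) th = t  (translations in the centered frame)
  th <- solve(Rh + diag(3), t$translation)
  fwd <- rigid_transform(matrix_to_euler(Rh), th, t$center)
  list(forward = fwd, backward = invert_transform(fwd))
}

# map 0-based voxel coordinates (n x 3) through a transform, in mm space
transform_points <- function(t, pts_vox, voxel_size) {
  M <- transform_matrix(t)
  mm <- sweep(pts_vox, 2L, voxel_size, `*`)
  out <- mm %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(mm), 3, byrow = TRUE)
  sweep(out, 2L, voxel_size, `/`)
}

#' Resample a volume through a rigid transform
#'
#' Produces the moved image on the same grid: the output at grid point `y`
#' is the input interpolated at `T^{-1}(y)` (trilinear; out-of-field voxels
#' are zero). Applying `resample_volume(x, T)` therefore moves the image
#' content forward by `T`. For 4D input every 3D sub-volume receives the
#' same transform.
#'
#' @param vol 3D or 4D array.
#' @param t a `rigid_transform` (mm units).
#' @param voxel_size voxel edges in mm.
#' @return array of the same shape.
#' @export
resample_volume <- function(vol, t, voxel_size = c(1, 1, 1)) {
  dm <- dim(vol)
  nd <- length(dm)
  stopifnot(nd %in% c(3L, 4L))
  dm3 <- dm[1:3]
  g <- voxel_grid(dm3)
  pts <- cbind(as.vector(g$x), as.vector(g$y), as.vector(g$z))
  src <- transform_points(invert_transform(t), pts, voxel_size)
  interp3 <- function(a) trilinear(a, src)
  if (nd == 3L) {
    array(interp3(vol), dim = dm3)
  } else {
    out <- vapply(seq_len(dm[4]), function(k) interp3(vol[, , , k]),
                  numeric(prod(dm3)))
    array(out, dim = dm)
  }
}

# trilinear interpolation of a 3D array at 0-based real coordinates (n x 3);
# outside the grid -> 0
trilinear <- function(a, pts) {
  dm <- dim(a)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  get <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= dm[1] - 1 & iy >= 0 & iy <= dm[2] - 1 &
          iz >= 0 & iz <= dm[3] - 1
    v <- numeric(length(ix))
    lin <- (ix[ok] + 1) + iy[ok] * dm[1] + iz[ok] * dm[1] * dm[2]
    v[ok] <- a[lin]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      vv <- get(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      val[nz] <- val[nz] + w[nz] * vv
    }
  }
  val
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Angles are stored in degrees, translations in mm, together with the 4x4
#' homogeneous matrix.
#'
#' @param t a `rigid_transform`.
#' @param path output (input) file.
#' @return `write_transform_json` returns `path` invisibly;
#'   `read_transform_json` returns a `rigid_transform`.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(list(angles_deg = t$angles * 180 / pi,
                            translation_mm = t$translation,
                            center_mm = t$center,
                            matrix = transform_matrix(t)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$angles_deg * pi / 180, j$translation_mm, j$center_mm)
}
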