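# Diffusion tensor estimation and scalar maps (FA, MD, AD, RD).

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA is the normalized dispersion of the three tensor eigenvalues,
#' `sqrt(((l1-l2)^2 + (l1-l3)^2 + (l3-l2)^2) / (2*(l1^2+l2^2+l3^2)))`,
#' ranging from 0 (isotropic diffusion) to 1 (diffusion along a single axis).
#' All-zero eigenvalue triples are defined as FA = 0.
#'
#' @param l1,l2,l3 eigenvalues in mm2/s (vectors are recycled elementwise).
#' @return numeric vector of FA values in `[0, 1]`.
#' @examples
#' fa_from_eigenvalues(1, 1, 1)              # 0
#' fa_from_eigenvalues(1, 0, 0)              # 1
#' fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.3e-3)  # ~0.799
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  num <- (l1 - l2)^2 + (l1 - l3)^2 + (l3 - l2)^2
  den <- 2 * (l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, sqrt(num / den), 0)
  pmin(pmax(fa, 0), 1)
}

# Closed-form eigenvalues of many symmetric 3x3 matrices at once.
# D: n x 6 matrix with columns (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
# Returns n x 3 matrix, eigenvalues sorted descending.
eigvals_sym3 <- function(D) {
  a11 <- D[, 1]; a22 <- D[, 2]; a33 <- D[, 3]
  a12 <- D[, 4]; a13 <- D[, 5]; a23 <- D[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  # B = (A - qI)/p; r = det(B)/2
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) -
          a12 * (a12 * b33 - a23 * a13) +
          a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  iso <- p2 <= .Machine$double.eps * pmax(q^2, 1e-300)
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  cbind(l1, l2, l3, deparse.level = 0)
}

# Principal eigenvector (for l1) of symmetric 3x3 matrices, vectorized.
principal_eigvec <- function(D, l1) {
  r1 <- cbind(D[, 1] - l1, D[, 4], D[, 5])
  r2 <- cbind(D[, 4], D[, 2] - l1, D[, 6])
  r3 <- cbind(D[, 5], D[, 6], D[, 3] - l1)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c12 <- cross(r1, r2); c13 <- cross(r1, r3); c23 <- cross(r2, r3)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- pmax(n12, n13, n23)
  v <- c12
  pick13 <- n13 == best; v[pick13, ] <- c13[pick13, ]
  pick23 <- n23 == best & !pick13; v[pick23, ] <- c23[pick23, ]
  nrm <- sqrt(rowSums(v^2))
  degen <- nrm < 1e-30
  v[degen, ] <- rep(c(1, 0, 0), each = sum(degen))
  nrm[degen] <- 1
  v / nrm
}

# Design matrix of the log-linear tensor model: ln S = X beta,
# beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Brain mask from a b0 image
#'
#' Thresholds the unweighted (b = 0) image at a fraction of its robust
#' maximum (the 99th percentile of positive voxels) and keeps the largest
#' 26-connected component.
#'
#' @param b0 3D numeric array, nonnegative.
#' @param frac threshold as a fraction of the robust maximum (default 0.1).
#' @return logical 3D array.
#' @export
brain_mask <- function(b0, frac = 0.1) {
  stopifnot(is.array(b0), length(dim(b0)) == 3L)
  if (any(b0 < 0)) stop("b0 image must be nonnegative")
  pos <- b0[b0 > 0]
  if (length(pos) == 0L) stop("empty brain mask: b0 image is identically zero")
  thr <- frac * stats::quantile(pos, 0.99, names = FALSE)
  mask <- b0 > thr
  if (!any(mask)) stop("empty brain mask at threshold ", signif(thr, 4))
  lab <- label_components(mask, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Fit the diffusion tensor voxelwise
#'
#' Weighted log-linear least-squares fit of the monoexponential tensor model
#' `ln S = ln S0 - b g' D g` in every voxel of `mask`. Weights default to the
#' squared observed signal (the standard first-order variance correction for
#' log-transformed Rician/Gaussian noise); `weighting = "none"` gives ordinary
#' least squares via a single shared pseudoinverse. S0 is estimated jointly as
#' the regression intercept.
#'
#' @param dwi 4D array (x, y, z, volume).
#' @param scheme [make_gradient_scheme()] object matching dim 4 of `dwi`.
#' @param mask logical 3D array; voxels outside are skipped.
#' @param weighting `"signal2"` (default) or `"none"`.
#' @return object of class `tensor_field`: list with `coef` (n_mask x 6 tensor
#'   coefficients Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm2/s), `s0` (n_mask),
#'   `mask`, `dim`, `voxel_size` attribute untouched.
#' @export
fit_tensor <- function(dwi, scheme, mask, weighting = c("signal2", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(dim(dwi)) == 4L, inherits(scheme, "gradient_scheme"))
  nvol <- dim(dwi)[4L]
  if (nvol != length(scheme$bvalues))
    stop("dwi has ", nvol, " volumes but the scheme describes ", length(scheme$bvalues))
  nz <- scheme$bvalues > 0
  if (sum(nz) < 6L || !any(!nz))
    stop("scheme deficiency: need >= 6 diffusion-weighted directions and >= 1 b0 volume")
  X <- tensor_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("scheme deficiency: singular design matrix (directions do not span ",
         "the 6 tensor components)")
  vx <- which(mask)
  nmask <- length(vx)
  if (nmask == 0L) stop("empty mask")
  V <- prod(dim(dwi)[1:3])
  S <- matrix(dwi, nrow = V)[vx, , drop = FALSE]   # n_mask x n_vol
  s0_scale <- max(S)
  S <- pmax(S, 1e-6 * s0_scale)                    # log-safety floor
  Y <- log(S)

  if (weighting == "none") {
    beta <- t(qr.coef(qrX, t(Y)))
  } else {
    W <- S^2
    npar <- 7L
    pairs <- which(upper.tri(diag(npar), diag = TRUE), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    P <- X[, pairs[, 1L], drop = FALSE] * X[, pairs[, 2L], drop = FALSE]
    A <- W %*% P                                   # n_mask x 28
    rhs <- (W * Y) %*% X                           # n_mask x 7
    beta <- .batch_solve_sym7(A, rhs, pairs - 1L)
    bad <- !is.finite(beta[, 1L])
    if (any(bad)) beta[bad, ] <- t(qr.coef(qrX, t(Y[bad, , drop = FALSE])))
  }
  structure(list(coef = beta[, 2:7, drop = FALSE],
                 s0 = exp(beta[, 1L]),
                 mask = mask, dim = dim(dwi)[1:3]),
            class = "tensor_field")
}

#' Eigensystem of a fitted tensor field
#'
#' Closed-form (Cardano) eigenvalues of each voxel's symmetric tensor, sorted
#' descending, with negative eigenvalues clamped to a small positive floor
#' (1e-12 mm2/s) so the scalar metrics stay defined, plus the unit principal
#' eigenvector.
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @param clamp_floor eigenvalue floor in mm2/s.
#' @return object of class `eigen_system`: `values` (n_mask x 3, descending),
#'   `vectors` (n_mask x 3 principal direction), `mask`, `dim`.
#' @export
tensor_eigensystem <- function(tf, clamp_floor = 1e-12) {
  stopifnot(inherits(tf, "tensor_field"))
  ev <- eigvals_sym3(tf$coef)
  vec <- principal_eigvec(tf$coef, ev[, 1L])
  ev <- pmax(ev, clamp_floor)
  structure(list(values = ev, vectors = vec, mask = tf$mask, dim = tf$dim),
            class = "eigen_system")
}

#' Scalar diffusion maps from an eigensystem
#'
#' FA per [fa_from_eigenvalues()]; MD = (l1+l2+l3)/3; AD = l1 (axial);
#' RD = (l2+l3)/2 (radial). Values outside the brain mask are 0 by
#' convention, so hemispheric averages never include background.
#'
#' @param eig an `eigen_system` from [tensor_eigensystem()].
#' @param voxel_size voxel edge lengths in mm, stored in each map.
#' @return named list of `scalar_map` objects (`FA`, `MD`, `AD`, `RD`), each
#'   a list with `data` (3D array), `metric`, `voxel_size`.
#' @export
scalar_maps <- function(eig, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(eig, "eigen_system"))
  l1 <- eig$values[, 1L]; l2 <- eig$values[, 2L]; l3 <- eig$values[, 3L]
  vals <- list(FA = fa_from_eigenvalues(l1, l2, l3),
               MD = (l1 + l2 + l3) / 3,
               AD = l1,
               RD = (l2 + l3) / 2)
  vx <- which(eig$mask)
  out <- lapply(names(vals), function(m) {
    a <- array(0, dim = eig$dim)
    a[vx] <- vals[[m]]
    scalar_map(a, metric = m, voxel_size = voxel_size)
  })
  names(out) <- names(vals)
  out
}

#' Construct a scalar map
#'
#' Light container for one 3D scalar image (FA, MD, AD or RD) plus voxel-size
#' metadata.
#'
#' @param data 3D numeric array.
#' @param metric one of `"FA"`, `"MD"`, `"AD"`, `"RD"` or another label.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(data, metric = "FA", voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(voxel_size) == 3L)
  structure(list(data = data, metric = metric,
                 voxel_size = as.numeric(voxel_size)),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map %s> %s voxels at %s mm, range [%.4g, %.4g]\n",
              x$metric, paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write scalar maps as NIfTI with metric suffixes
#'
#' @param maps named list from [scalar_maps()].
#' @param prefix output path prefix; files are written as
#'   `<prefix>_<METRIC>.nii.gz`.
#' @return character vector of written paths, invisibly.
#' @export
write_scalar_maps <- function(maps, prefix) {
  paths <- vapply(maps, function(m) {
    p <- paste0(prefix, "_", m$metric, ".nii.gz")
    write_nifti(m$data, p, voxel_size = m$voxel_size)
    p
  }, character(1))
  invisible(paths)
}
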