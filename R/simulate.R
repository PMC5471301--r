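# Forward simulation of the diffusion-weighted signal.

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Generates the monoexponential tensor signal `S = S0 * exp(-b g' D g)` per
#' voxel and gradient, then applies magnitude-MRI (Rician) noise: the output
#' is `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, noise_sigma^2)`.
#' Gaussian additive noise is available for analytic checks. Background
#' voxels have zero signal (pure noise floor).
#'
#' @param phantom a `dti_phantom` from [build_phantom()].
#' @param scheme a `gradient_scheme`; defaults to the clinical 48-direction
#'   b = 800 s/mm2 protocol with 4 b0 volumes.
#' @param noise_sigma noise standard deviation in signal units; defaults to
#'   the phantom's. Zero gives the noiseless signal.
#' @param seed optional integer; when given, the RNG state is set locally so
#'   the simulation is reproducible and the caller's RNG stream is untouched.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @return 4D array (x, y, z, volume).
#' @export
simulate_dwi <- function(phantom, scheme = make_gradient_scheme(),
                         noise_sigma = NULL, seed = NULL,
                         noise_model = c("rician", "gaussian")) {
  stopifnot(inherits(phantom, "dti_phantom"), inherits(scheme, "gradient_scheme"))
  noise_model <- match.arg(noise_model)
  if (is.null(noise_sigma)) noise_sigma <- phantom$noise_sigma
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")

  dm <- phantom$grid_shape
  V <- prod(dm)
  nvol <- length(scheme$bvalues)
  vx <- which(phantom$tissue > 0L)
  D <- phantom$tensor[vx, , drop = FALSE]
  gmat <- scheme$directions
  b <- scheme$bvalues
  # quadratic form g' D g expressed on the 6 unique coefficients
  Q <- rbind(gmat[, 1]^2, gmat[, 2]^2, gmat[, 3]^2,
             2 * gmat[, 1] * gmat[, 2],
             2 * gmat[, 1] * gmat[, 3],
             2 * gmat[, 2] * gmat[, 3])          # 6 x nvol
  expo <- D %*% Q                                # n_tissue x nvol
  S <- phantom$s0 * exp(-sweep(expo, 2L, b, `*`))
  signal <- matrix(0, nrow = V, ncol = nvol)
  signal[vx, ] <- S

  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
      on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
              else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(as.integer(seed))
    }
    n <- length(signal)
    if (noise_model == "rician") {
      signal <- sqrt((signal + stats::rnorm(n, 0, noise_sigma))^2 +
                     stats::rnorm(n, 0, noise_sigma)^2)
    } else {
      signal <- signal + stats::rnorm(n, 0, noise_sigma)
    }
  }
  array(signal, dim = c(dm, nvol))
}

#' Compute FA/MD/AD/RD maps from a simulated or loaded acquisition
#'
#' Convenience wrapper chaining [brain_mask()] on the mean b0,
#' [fit_tensor()], [tensor_eigensystem()] and [scalar_maps()].
#'
#' @param dwi 4D array.
#' @param scheme matching `gradient_scheme`.
#' @param voxel_size mm, stored in the output maps.
#' @param mask optional logical array; computed from the mean b0 if `NULL`.
#' @param weighting passed to [fit_tensor()].
#' @return list with `maps` (from [scalar_maps()]), `mask`, `tensor_field`.
#' @export
dwi_to_maps <- function(dwi, scheme, voxel_size = c(1, 1, 1), mask = NULL,
                        weighting = "signal2") {
  b0 <- scheme$bvalues == 0
  b0map <- apply(dwi[, , , b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- brain_mask(b0map)
  tf <- fit_tensor(dwi, scheme, mask, weighting = weighting)
  eig <- tensor_eigensystem(tf)
  list(maps = scalar_maps(eig, voxel_size = voxel_size), mask = mask,
       tensor_field = tf, b0 = b0map)
}
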