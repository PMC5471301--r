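# Diffusion gradient schemes.

new_gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  dimnames(directions) <- NULL
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("directions and bvalues must have one entry per volume")
  if (any(bvalues < 0)) stop("b-values must be nonnegative")
  nz <- bvalues > 0
  if (any(nz)) {
    nrm <- sqrt(rowSums(directions[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("nonzero-b directions must be unit vectors")
  }
  structure(list(directions = directions, bvalues = bvalues,
                 n_b0 = sum(!nz)),
            class = "gradient_scheme")
}

#' Build a diffusion gradient scheme
#'
#' Constructs a quasi-uniform single-shell gradient scheme: `n_b0` unweighted
#' (b = 0) volumes followed by `n_directions` unit direction vectors placed by
#' a deterministic golden-section spiral on the sphere, all at b-value `b`.
#' The default (48 directions at b = 800 s/mm2 plus 4 b0 volumes, 52 volumes
#' total) mirrors a typical 1.5 T clinical DTI protocol.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; the
#'   tensor has 6 free parameters).
#' @param b diffusion weighting in s/mm2 for the weighted volumes.
#' @param n_b0 number of b = 0 volumes.
#' @return object of class `gradient_scheme` with `directions` (n_volumes x 3
#'   matrix, zero rows for b0), `bvalues` (per volume) and `n_b0`.
#' @examples
#' sch <- make_gradient_scheme(48, 800, 4)
#' length(sch$bvalues)  # 52
#' @export
make_gradient_scheme <- function(n_directions = 48L, b = 800, n_b0 = 4L) {
  if (n_directions < 6L)
    stop("invalid scheme: at least 6 diffusion directions are required")
  if (b <= 0) stop("b must be positive for the weighted shell")
  if (n_b0 < 0L) stop("n_b0 must be nonnegative")
  i <- seq_len(n_directions) - 0.5
  z <- 1 - 2 * i / n_directions
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  directions <- rbind(matrix(0, n_b0, 3L), dirs)
  bvalues <- c(rep(0, n_b0), rep(b, n_directions))
  new_gradient_scheme(directions, bvalues)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes: %d b0 + %d directions at b = %g s/mm^2\n",
              length(x$bvalues), x$n_b0, length(x$bvalues) - x$n_b0,
              max(x$bvalues)))
  invisible(x)
}
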