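# Shared fixtures: small schemes and desk-scale phantoms built in code.

small_scheme <- function(n_dir = 12L, b = 800, n_b0 = 1L)
  make_gradient_scheme(n_dir, b, n_b0)

small_phantom <- function(tumor = "none", f = 0, grid = c(16L, 16L, 8L),
                          radius = 6, ...) {
  build_phantom(phantom_spec(grid_shape = grid, voxel_size = c(2, 2, 2.8),
                             tumor_hemisphere = tumor, tumor_radius = radius,
                             fa_reduction_factor = f, ...))
}

# independent enumeration oracle for the two-sided Mann-Whitney p-value:
# all C(n1+n2, n1) group labelings of the pooled sample
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  center <- n1 * length(b) / 2
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2L, function(idx) ustat(pooled[idx], pooled[-idx]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

# brute-force voxel-loop delta-FA oracle (independent of global_delta)
bruteforce_delta <- function(fa, hemis, healthy, tumor_side, thr = 0.2) {
  vals_h <- c(); vals_t <- c()
  dm <- dim(fa)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- fa[i, j, k]
    if (v > thr) {
      if (hemis[[healthy]][i, j, k]) vals_h <- c(vals_h, v)
      if (hemis[[tumor_side]][i, j, k]) vals_t <- c(vals_t, v)
    }
  }
  mean(vals_h) - mean(vals_t)
}

# flood-fill-free component oracle via igraph on the voxel adjacency graph
igraph_components <- function(mask, connectivity = 26L) {
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dim = dim(mask)))
  dm <- dim(mask)
  coords <- arrayInd(idx, dm)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  pos <- stats::setNames(seq_along(idx), idx)
  edges <- c()
  for (r in seq_along(idx)) {
    nb <- sweep(off, 2L, coords[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * dm[1] + (nb[, 3] - 1) * dm[1] * dm[2]
    lin <- lin[mask[lin]]
    for (l in lin) if (pos[[as.character(l)]] > r)
      edges <- c(edges, r, pos[[as.character(l)]])
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- array(0L, dim = dm)
  out[idx] <- comp
  out
}
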