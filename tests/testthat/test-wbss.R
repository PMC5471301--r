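test_that("smoothing preserves constants and is the identity at fwhm 0", {
  dm <- c(12L, 12L, 6L)
  mask <- hemidti:::sphere_mask(dm, (dm - 1) / 2, 9, c(2, 2, 2.8))
  img <- array(0, dim = dm); img[mask] <- 0.7
  sm <- smooth_volume(img, fwhm = 8, mask = mask, voxel_size = c(2, 2, 2.8))
  expect_lt(max(abs(sm[mask] - 0.7)), 1e-12)
  expect_true(all(sm[!mask] == 0))
  expect_identical(smooth_volume(img, fwhm = 0, mask = mask), img)
  expect_error(smooth_volume(img, fwhm = -1), "nonnegative")
})

test_that("impulse response matches the closed-form kernel value", {
  dm <- c(21L, 21L, 21L)
  mask <- array(TRUE, dim = dm)
  img <- array(0, dim = dm); img[11, 11, 11] <- 1
  vs <- c(2, 2, 2)
  sm <- smooth_volume(img, fwhm = 8, mask = mask, voxel_size = vs)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2          # 1.6986 voxels
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  k0 <- k[r + 1]
  expect_equal(sm[11, 11, 11], k0^3, tolerance = 1e-12)
})

test_that("mass renormalization preserves the masked mean exactly", {
  set.seed(5)
  dm <- c(14L, 12L, 8L)
  mask <- hemidti:::sphere_mask(dm, (dm - 1) / 2 + c(0.7, -0.4, 0.2), 10,
                                c(2, 2, 2.8))
  img <- array(0, dim = dm); img[mask] <- runif(sum(mask), 0.2, 0.9)
  sm <- smooth_volume(img, fwhm = 8, mask = mask, voxel_size = c(2, 2, 2.8),
                      renorm = "mass")
  expect_equal(mean(sm[mask]), mean(img[mask]), tolerance = 1e-9)
  # the two renormalizations agree deep in the interior of a large mask
  dm2 <- c(30L, 30L, 30L)
  mask2 <- array(TRUE, dim = dm2)
  img2 <- array(0.5, dim = dm2)
  img2[10:20, 10:20, 10:20] <- 0.8
  smn <- smooth_volume(img2, fwhm = 4, mask = mask2, voxel_size = c(2, 2, 2))
  smm <- smooth_volume(img2, fwhm = 4, mask = mask2, voxel_size = c(2, 2, 2),
                       renorm = "mass")
  core <- array(FALSE, dim = dm2); core[8:22, 8:22, 8:22] <- TRUE
  expect_equal(smn[core], smm[core], tolerance = 1e-10)
})

test_that("voxelwise test finds the effect where it was injected", {
  set.seed(21)
  dm <- c(10L, 8L, 4L)
  mask <- array(TRUE, dim = dm)
  effect <- array(0, dim = dm); effect[1:4, , ] <- 0.2    # left-side effect
  ga <- lapply(1:5, function(i) array(rnorm(prod(dm), 0.5, 0.02), dim = dm))
  gb <- lapply(1:5, function(i) array(rnorm(prod(dm), 0.5, 0.02), dim = dm) + effect)
  p <- voxelwise_test(ga, gb, mask)
  expect_true(all(p >= 0 & p <= 1))
  best <- arrayInd(which.min(p), dm)
  expect_lte(best[1], 4)
  # identical groups: p = 1 everywhere (degenerate ties)
  p1 <- voxelwise_test(ga, ga, mask)
  expect_true(all(p1 == 1))
  expect_error(voxelwise_test(ga[1], gb, mask), "at least 2")
})

test_that("voxelwise p equals the scalar test per voxel, both tests", {
  set.seed(22)
  dm <- c(4L, 3L, 2L)
  mask <- array(TRUE, dim = dm)
  ga <- lapply(1:4, function(i) array(rnorm(prod(dm)), dim = dm))
  gb <- lapply(1:6, function(i) array(rnorm(prod(dm), 0.3), dim = dm))
  p <- voxelwise_test(ga, gb, mask)
  for (v in c(1L, 7L, 24L)) {
    a <- vapply(ga, function(m) m[v], numeric(1))
    b <- vapply(gb, function(m) m[v], numeric(1))
    expect_equal(p[v], mann_whitney(a, b)$p, tolerance = 1e-12)
  }
  pt <- voxelwise_test(ga, gb, mask, test = "t-test")
  a <- vapply(ga, function(m) m[2], numeric(1))
  b <- vapply(gb, function(m) m[2], numeric(1))
  expect_equal(pt[2], stats::t.test(a, b)$p.value, tolerance = 1e-9)
})

test_that("BH-FDR matches a brute-force threshold search", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 10), 0.05)$n_significant, 0L)
  expect_true(fdr_correct(0.04, 0.05)$significant)
  expect_error(fdr_correct(numeric(0)), "empty")
  # brute force over all candidate thresholds, random inputs
  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(5:60, 1))^2
    alpha <- runif(1, 0.01, 0.2)
    got <- fdr_correct(p, alpha)
    m <- length(p); ps <- sort(p)
    ok <- which(ps <= seq_len(m) / m * alpha)
    want_thr <- if (length(ok)) ps[max(ok)] else 0
    expect_equal(got$threshold, want_thr)
    expect_equal(got$significant, p <= want_thr | (want_thr > 0 & p <= want_thr))
    # consistency with stats::p.adjust
    expect_equal(got$significant, stats::p.adjust(p, "BH") <= alpha)
    # FDR never declares more than uncorrected alpha
    expect_lte(got$n_significant, sum(p < alpha) + sum(p == alpha))
  }
})

test_that("cluster filtering honors the size threshold inclusively", {
  dm <- c(12L, 8L, 6L)
  m <- array(FALSE, dim = dm)
  m[1:2, 1:2, 1:2] <- TRUE                  # 8 voxels
  m[6:11, 1:5, 1:4] <- TRUE                 # 120 voxels
  r <- cluster_filter(m, min_cluster = 8L)
  expect_equal(sort(r$clusters$size), c(8L, 120L))
  r2 <- cluster_filter(m, min_cluster = 9L)
  expect_equal(r2$clusters$size, 120L)
  expect_false(any(r2$mask[1:2, , ]))
  # 600 vs 100 at threshold 512: exactly one survives
  big <- array(FALSE, dim = c(40L, 20L, 10L))
  big[1:10, 1:10, 1:6] <- TRUE              # 600
  big[30:39, 1:5, 1:2] <- TRUE              # 100
  r3 <- cluster_filter(big, min_cluster = 512L)
  expect_equal(nrow(r3$clusters), 1L)
  expect_equal(r3$clusters$size, 600L)
})

test_that("component labeling agrees with an igraph oracle on random masks", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (conn in c(6L, 26L)) {
    for (i in 1:6) {
      m <- array(runif(8 * 8 * 8) < 0.35, dim = c(8L, 8L, 8L))
      got <- label_components(m, connectivity = conn)
      want <- igraph_components(m, connectivity = conn)
      # same partition up to label permutation
      expect_equal(max(got), max(want))
      key <- paste(got[m], want[m])
      expect_equal(length(unique(key)), max(got))
    }
  }
})

test_that("scaled cluster threshold tracks the grid volume", {
  expect_equal(scaled_min_cluster(c(128L, 128L, 64L)), 512L)
  expect_equal(scaled_min_cluster(c(64L, 64L, 32L)), 64L)
  expect_equal(scaled_min_cluster(c(8L, 8L, 8L)), 5L)   # floor
})

test_that("the FDR null rarely fires across replicate phantom groups", {
  set.seed(55)
  dm <- c(6L, 6L, 4L)
  mask <- array(TRUE, dim = dm)
  nrep <- 500
  any_sig <- logical(nrep)
  for (r in seq_len(nrep)) {
    ga <- lapply(1:4, function(i) array(rnorm(prod(dm)), dim = dm))
    gb <- lapply(1:4, function(i) array(rnorm(prod(dm)), dim = dm))
    p <- voxelwise_test(ga, gb, mask)
    any_sig[r] <- fdr_correct(p[mask], 0.05)$n_significant > 0
  }
  alpha <- 0.05
  bound <- alpha + 2 * sqrt(alpha * (1 - alpha) / nrep)
  expect_lte(mean(any_sig), bound)
})

test_that("the full WBSS chain flags the affected hemisphere only", {
  set.seed(66)
  ph <- small_phantom(grid = c(16L, 16L, 8L))
  mask <- ph$tissue > 0L
  vs <- ph$voxel_size
  pre <- lapply(1:4, function(i) {
    a <- ph$true_fa + array(rnorm(prod(dim(mask)), 0, 0.01), dim = dim(mask))
    scalar_map(a * mask, "FA", vs)
  })
  eff <- array(0, dim = dim(mask)); eff[ph$hemispheres$right] <- -0.12
  post <- lapply(1:4, function(i) {
    a <- ph$true_fa + eff + array(rnorm(prod(dim(mask)), 0, 0.01), dim = dim(mask))
    scalar_map(a * mask, "FA", vs)
  })
  res <- wbss(pre, post, mask, fwhm = 6, min_cluster = 5L)
  expect_gt(sum(res$sig_mask & ph$hemispheres$right), 0)
  expect_true(all(res$sig_mask[mask == FALSE] == FALSE))
  expect_gte(min(res$clusters$clusters$size), 5L)
  # the effect is concentrated ipsilaterally: the most significant voxel is
  # on the affected side and the affected side dominates the count (smoothing
  # bleeds the effect a little across the midline, so not exclusively)
  best <- which(res$p_map == min(res$p_map))
  expect_true(any(ph$hemispheres$right[best]))
  expect_gt(sum(res$sig_mask & ph$hemispheres$right),
            sum(res$sig_mask & ph$hemispheres$left))
})
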