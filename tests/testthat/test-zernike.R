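# 3D Zernike moments and rotation-invariant descriptors.

test_that("descriptor_length counts valid (n, l) pairs", {
  # independent enumeration oracle
  count_pairs <- function(order) {
    cnt <- 0L
    for (n in 0:order) for (l in 0:n) if ((n - l) %% 2L == 0L) cnt <- cnt + 1L
    cnt
  }
  expect_identical(descriptor_length(15), 72L)
  expect_identical(descriptor_length(0), 1L)
  expect_identical(descriptor_length(2), 4L)   # (0,0),(1,1),(2,0),(2,2)
  for (ord in c(1, 3, 7, 10, 20)) {
    expect_identical(descriptor_length(ord), count_pairs(ord))
  }
  expect_error(descriptor_length(-1), "nonnegative")
  expect_error(descriptor_length(2.5), "nonnegative")
})

test_that("voxelize_points maps points to their nearest voxels", {
  # one point: only its footprint voxel is nonzero, at the grid center
  g <- voxelize_points(matrix(c(3, 4, 5), ncol = 3), dim = 16)
  expect_identical(sum(g$values != 0), 1L)
  nz <- which(g$values != 0, arr.ind = TRUE)
  expect_true(all(abs(nz - 8.5) <= 0.51))

  # all points identical: one nonzero voxel cluster at the center
  pts <- matrix(rep(c(1, 2, 3), 5), ncol = 3, byrow = TRUE)
  g2 <- voxelize_points(pts, values = c(1, 2, 3, 4, 5), dim = 16)
  expect_identical(sum(g2$values != 0), 1L)
  expect_equal(g2$values[g2$values != 0], 3)   # collisions averaged

  # random cloud: nonzero count equals an independent nearest-voxel map
  set.seed(11)
  pts <- matrix(rnorm(300), ncol = 3)
  dim <- 24L
  g3 <- voxelize_points(pts, dim = dim, ball_fill = 0.7)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sc <- 0.7 / sqrt(max(rowSums(cen^2)))
  idx <- round((cen * sc + 1) * dim / 2 + 0.5)
  expect_identical(sum(g3$values != 0), nrow(unique(idx)))

  expect_error(voxelize_points(matrix(numeric(0), ncol = 3)), "at least one")
  expect_error(voxelize_points(matrix(c(1, NA, 2), ncol = 3)), "finite")
  expect_error(voxelize_points(matrix(1:3, ncol = 3), dim = 4), "at least 8")
  expect_error(voxelize_points(matrix(1:3, ncol = 3), ball_fill = 1.5),
               "ball_fill")
})

test_that("zernike_moments match brute-force integration of the basis", {
  set.seed(21)
  g <- voxelize_points(matrix(rnorm(150), ncol = 3), dim = 16)
  mo <- zernike_moments(g, order = 6L)
  bf <- brute_force_moments(g, 6L)
  merged <- merge(as.data.frame(mo), bf, by = c("n", "l", "m"))
  scale <- max(Mod(merged$omega.x))
  expect_lt(max(Mod(merged$omega.x - merged$omega.y)) / scale, 1e-6)
})

test_that("zernike_moments handle degenerate and symmetric inputs", {
  z <- voxel_grid(array(0, dim = rep(12, 3)))
  mo <- zernike_moments(z, 4L)
  expect_true(all(Mod(mo$omega) == 0))

  # radially symmetric ball: moments with l > 0 vanish
  ball <- make_voxel_object("ball", dim = 32)
  mo <- zernike_moments(ball, 6L)
  l0 <- max(Mod(mo$omega[mo$l == 0]))
  expect_lt(max(Mod(mo$omega[mo$l > 0])) / l0, 1e-4)

  # conjugate symmetry holds for all computed moments
  set.seed(3)
  g <- voxelize_points(matrix(rnorm(90), ncol = 3), dim = 16)
  mo <- zernike_moments(g, 8L)
  for (i in which(mo$m > 0)) {
    j <- which(mo$n == mo$n[i] & mo$l == mo$l[i] & mo$m == -mo$m[i])
    expect_equal(mo$omega[j], (-1)^mo$m[i] * Conj(mo$omega[i]))
  }

  # unnormalized grids are rejected
  bad <- voxel_grid(array(1, dim = rep(12, 3)))
  expect_error(zernike_moments(bad, 4L), "unit ball")
  expect_error(zernike_moments(z, 21L), "not supported")
})

test_that("invariants have the contracted length and respond linearly", {
  z <- voxel_grid(array(0, dim = rep(12, 3)))
  d0 <- zernike_invariants(zernike_moments(z, 15L))
  expect_length(d0, 72L)
  expect_true(all(d0 == 0))

  set.seed(4)
  g <- voxelize_points(matrix(rnorm(120), ncol = 3), dim = 16)
  d1 <- zernike_descriptor(g, 15L)
  expect_length(d1, 72L)
  expect_true(all(d1 >= 0))

  # linearity: descriptor of a*f equals a*descriptor(f)
  g3 <- g
  g3$values <- 3.5 * g$values
  expect_equal(as.numeric(zernike_descriptor(g3, 15L)), 3.5 * as.numeric(d1),
               tolerance = 1e-12)
})

test_that("descriptors are invariant under 90-degree grid rotations", {
  set.seed(6)
  for (rep in 1:3) {
    g <- voxelize_points(matrix(rnorm(240), ncol = 3), dim = 24)
    d1 <- as.numeric(zernike_descriptor(g, 12L))
    # rotate the raw array about z then x
    gz <- g; gz$values <- aperm(g$values[, g$dim:1, ], c(2, 1, 3))
    gx <- g; gx$values <- aperm(g$values[, , g$dim:1], c(1, 3, 2))
    for (gr in list(gz, gx)) {
      d2 <- as.numeric(zernike_descriptor(gr, 12L))
      expect_lt(max(abs(d1 - d2)) / max(d1), 1e-9)
    }
  }
})

test_that("descriptor serialization round-trips bit-exactly", {
  set.seed(8)
  x <- matrix(rnorm(3 * 72) * 10^runif(3 * 72, -12, 3), nrow = 3)
  for (fmt in c("text", "binary")) {
    path <- tempfile()
    write_descriptors(x, path, order = 15L,
                      channels = c("shape", "ele", "hyd"), format = fmt)
    y <- read_descriptors(path, format = fmt)
    expect_identical(unname(y[, ]), unname(x))
    expect_identical(attr(y, "order"), 15L)
    expect_identical(rownames(y), c("shape", "ele", "hyd"))
    unlink(path)
  }
})

test_that("gaussian splat voxelization is stable and frame-pinnable", {
  set.seed(13)
  pts <- matrix(rnorm(90, sd = 2), ncol = 3)
  g <- voxelize_points(pts, dim = 32, sigma = 0.8, center = c(0, 0, 0),
                       scale_radius = 8)
  expect_s3_class(g, "voxel_grid")
  # splat conserves total deposited mass inside the ball (taper aside)
  expect_gt(sum(g$values), 0)
  # a small perturbation moves the descriptor much less than under
  # single-voxel marking
  pts2 <- pts + matrix(rnorm(90, sd = 0.15), ncol = 3)
  g2 <- voxelize_points(pts2, dim = 32, sigma = 0.8, center = c(0, 0, 0),
                        scale_radius = 8)
  dsm <- sqrt(sum((unitize(as.numeric(zernike_descriptor(g, 15L))) -
                     unitize(as.numeric(zernike_descriptor(g2, 15L))))^2))
  h1 <- voxelize_points(pts, dim = 32, center = c(0, 0, 0), scale_radius = 8)
  h2 <- voxelize_points(pts2, dim = 32, center = c(0, 0, 0), scale_radius = 8)
  dhard <- sqrt(sum((unitize(as.numeric(zernike_descriptor(h1, 15L))) -
                       unitize(as.numeric(zernike_descriptor(h2, 15L))))^2))
  expect_lt(dsm, dhard)
})
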