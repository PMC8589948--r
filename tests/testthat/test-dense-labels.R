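# Independent scalar oracle for the dense-label coefficient: explicit
# clamp -> product sequence, no vectorization shared with the
# implementation.
eq1_oracle <- function(d_max, d_j, dz, h) {
  if (d_j > d_max) d_j <- d_max
  frac <- abs(dz / h)
  f <- if (frac >= 1) 0 else 1 - tan(frac * pi / 2)
  if (f < 0) f <- 0
  p <- (d_max - d_j) * f
  if (p < 0) p <- 0
  p
}

test_that("compute_centroid is the brute-force voxel mean", {
  m <- array(FALSE, c(10, 10, 10))
  m[6, 7, 8] <- TRUE
  expect_equal(unname(compute_centroid(m)), c(5, 6, 7))

  cube <- array(TRUE, c(10, 10, 10))
  expect_equal(unname(compute_centroid(cube)), c(4.5, 4.5, 4.5))

  # L-shaped mask: enumerate voxels and average
  L <- array(FALSE, c(8, 8, 8))
  vox <- rbind(cbind(1:8, 1, 1), cbind(8, 2:5, 1))  # 12 voxels, 1-based
  L[vox] <- TRUE
  expect_equal(unname(compute_centroid(L)), unname(colMeans(vox) - 1))

  expect_error(compute_centroid(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("estimate_geometry recovers extent and 95th-percentile radius", {
  ball <- ball_mask(10)
  g <- estimate_geometry(ball)
  expect_equal(g$h, 21)
  expect_gte(g$d_max, 9)
  expect_lte(g$d_max, 10)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  gs <- estimate_geometry(single)
  expect_equal(gs$h, 1)
  expect_equal(gs$d_max, 1)  # degenerate floor

  disc <- array(FALSE, c(1, 21, 21))
  disc[1, , ] <- outer((0:20 - 10)^2, (0:20 - 10)^2, "+") <= 64
  gd <- estimate_geometry(disc)
  expect_equal(gd$h, 1)
  expect_gte(gd$d_max, 7.3)
  expect_lte(gd$d_max, 8)
})

test_that("eq1 coefficient matches the scalar oracle on a randomized grid", {
  set.seed(42)
  n <- 1000
  d_max <- runif(n, 1, 40)
  d_j <- runif(n, 0, 60)
  h <- runif(n, 5, 40)
  dz <- runif(n, -1.5, 1.5) * h
  got <- eq1_coefficient(d_max, d_j, dz, h)
  want <- mapply(eq1_oracle, d_max, d_j, dz, h)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("eq1 boundary values and monotonicity hold", {
  expect_equal(eq1_coefficient(15, 0, 0, 20), 15)
  expect_equal(eq1_coefficient(15, 15, 0, 20), 0)
  expect_equal(eq1_coefficient(15, 20, 0, 20), 0)     # clamp
  expect_equal(eq1_coefficient(20, 10, 4, 16),
               10 * (1 - tan(pi / 8)), tolerance = 1e-12)
  expect_equal(eq1_coefficient(15, 3, 10, 20), 0)     # |dz| = h/2
  expect_equal(eq1_coefficient(15, 3, 25, 20), 0)     # past the pole

  d <- seq(0, 25, by = 0.5)
  v <- eq1_coefficient(20, d, 2, 16)
  expect_true(all(diff(v) <= 1e-12))
  dz <- seq(0, 12, by = 0.25)
  v2 <- eq1_coefficient(20, 5, dz, 16)
  expect_true(all(diff(v2) <= 1e-12))
})

test_that("densify_vertebra scales the coefficient to 0..255", {
  ball <- ball_mask(8)
  cc <- compute_centroid(ball)
  g <- estimate_geometry(ball, cc)
  dv <- densify_vertebra(ball, cc, g)
  expect_true(all(dv >= 0 & dv <= 255))
  expect_true(all(dv[!ball] == 0))
  center <- round(cc) + 1
  expect_gt(dv[center[1], center[2], center[3]], 250)
  # voxels at the clamp distance score zero
  idx <- which(ball, arr.ind = TRUE)
  d <- sqrt(rowSums((t(t(idx) - 1) - matrix(cc, nrow(idx), 3, byrow = TRUE))^2))
  far <- idx[d >= g$d_max, , drop = FALSE]
  expect_true(all(dv[far] == 0))
  # spot value from the scalar oracle
  expect_equal(eq1_coefficient(20, 10, 4, 16) / 20 * 255, 74.68787,
               tolerance = 1e-4)
})

test_that("densify_spine equals per-vertebra output and is order-invariant", {
  ph <- small_phantom(n = 3, seed = 21, noise_sd = 0)
  dense <- densify_spine(ph$labels, ph$centroids)
  expect_true(all(dense$data >= 0 & dense$data <= 255))
  # disjoint supports: restriction to each vertebra equals its own encoding
  for (i in 1:3) {
    m <- ph$labels$data == i
    cc <- as.numeric(ph$centroids[i, c("z", "y", "x")])
    solo <- densify_vertebra(m, cc, estimate_geometry(m, cc))
    expect_equal(dense$data[m], solo[m], tolerance = 1e-12)
  }
  # processing order must not matter (max is commutative)
  perm <- densify_spine(ph$labels, ph$centroids[c(3, 1, 2), ])
  expect_equal(perm$data, dense$data)
  # within each vertebra the maximum sits on the centroid slice
  for (i in 1:3) {
    m <- ph$labels$data == i
    masked <- dense$data * m
    zmax <- which.max(apply(masked, 1, max)) - 1
    expect_equal(zmax, round(ph$centroids$z[i]))
  }
})

test_that("densify_spine rejects centroids for missing labels", {
  ph <- small_phantom(n = 2, seed = 3)
  bad <- rbind(ph$centroids,
               data.frame(vertebra_id = 9, z = 1, y = 1, x = 1))
  expect_error(densify_spine(ph$labels, bad), "absent")
})
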