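test_that("slice stacks zero-fill missing neighbors", {
  ph <- small_phantom(n = 2, seed = 8)
  v <- ph$image
  s0 <- build_slice_stack(v, 0, 4)
  expect_equal(dim(s0)[3], 9)
  expect_true(all(s0[, , 1:4] == 0))
  expect_equal(s0[, , 5], v$data[1, , ])
  # interior slice: channel c holds slice z - k + (c - 1)
  z <- 10
  si <- build_slice_stack(v, z, 4)
  for (c in 1:9) expect_equal(si[, , c], v$data[z - 4 + c, , ])
  s1 <- build_slice_stack(v, 3, 0)
  expect_equal(dim(s1)[3], 1)
  expect_equal(s1[, , 1], v$data[4, , ])
  expect_error(build_slice_stack(v, -1, 4), "range")
  expect_error(build_slice_stack(v, dim(v$data)[1], 4), "range")
})

test_that("predict_dense returns a 0..255 map of the input shape", {
  ph <- generate_spine_phantom(spine_phantom_spec(
    n_vertebrae = 1, body_radius_mm = 9, body_height_mm = 14,
    process_length_mm = 6, seed = 3))
  # crop to a pool-friendly size
  v <- volume(ph$image$data[1:20, 1:32, 1:24])
  net <- build_dense_unet(net_config(2, in_channels = 5, depth = 3,
                                     base_filters = 1), seed = 4)
  L <- predict_dense(v, net)
  expect_equal(dim(L$data), dim(v$data))
  expect_true(all(L$data >= 0 & L$data <= 255))
  L2 <- predict_dense(v, net)
  expect_identical(L$data, L2$data)  # inference determinism
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  x <- seq(0, 5, length.out = 60)
  cubic <- 1 - 2 * x + 0.7 * x^2 + 0.3 * x^3
  expect_lt(max(abs(smooth_profile(cubic, 11, 3) - cubic)), 1e-9)
  const <- rep(4.2, 40)
  expect_lt(max(abs(smooth_profile(const, 11, 2) - const)), 1e-9)
  expect_error(smooth_profile(const, 10, 2), "odd")
  expect_error(smooth_profile(const, 11, 11), "polyorder")
  expect_error(smooth_profile(rep(1, 5), 11, 2), "length")
})

test_that("smoothing matches a per-window polynomial-fit oracle and damps impulses", {
  set.seed(31)
  p <- runif(41)
  sm <- smooth_profile(p, 11, 2)
  # oracle: local least-squares quadratic fit evaluated at the window center
  for (i in c(6, 15, 27, 36)) {
    win <- (i - 5):(i + 5)
    fit <- lm(y ~ poly(t, 2, raw = TRUE), data.frame(y = p[win], t = win))
    expect_equal(sm[i], unname(predict(fit, data.frame(t = i))),
                 tolerance = 1e-8)
  }
  impulse <- c(rep(0, 20), 1, rep(0, 20))
  expect_lt(max(smooth_profile(impulse, 11, 2)), 1)
})

test_that("peak finding reports modes with height and separation rules", {
  expect_identical(find_peak_slices(rep(0, 50)), integer(0))
  z <- 0:99
  two <- exp(-(z - 25)^2 / 18) + 0.9 * exp(-(z - 70)^2 / 18)
  expect_equal(find_peak_slices(two), c(25L, 70L))
  # sub-threshold bump is dropped
  three <- two + 0.05 * exp(-(z - 48)^2 / 8)
  expect_equal(find_peak_slices(three), c(25L, 70L))
  # plateaus count once, at their center
  flat <- c(rep(0, 10), rep(1, 5), rep(0, 30))
  expect_equal(find_peak_slices(flat), 12L)
  # closer than min_separation: the higher peak wins
  close <- exp(-(z - 40)^2 / 8) + 0.8 * exp(-(z - 45)^2 / 8)
  got <- find_peak_slices(close, min_separation = 10)
  expect_length(got, 1)
  expect_lte(abs(got - 41L), 1L)
})

test_that("peak slices of ground-truth dense labels sit on the centroid slices", {
  ph <- small_phantom(n = 3, seed = 14)
  dense <- densify_spine(ph$labels, ph$centroids)
  prof <- smooth_profile(max_profile(dense), 11, 3)
  peaks <- find_peak_slices(prof)
  expect_length(peaks, 3)
  expect_true(all(abs(peaks - round(ph$centroids$z)) <= 2))
})

test_that("circle fitting is exact on noiseless circles", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  fit <- fit_circle_kasa(-3 + 7 * sin(th), 10 + 7 * cos(th))
  expect_equal(unname(fit), c(-3, 10, 7), tolerance = 1e-6)
  expect_error(fit_circle_kasa(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_circle_kasa(c(1, 2, 3), c(1, 2, 3)), "collinear")
})

test_that("in-plane fitting recovers the center of a radial cone", {
  r <- sqrt(outer((0:127 - 64)^2, (0:127 - 64)^2, "+"))
  cone <- pmax(255 - 4 * r, 0)
  ctr <- fit_inplane_center(cone)
  expect_lt(max(abs(ctr - c(64, 64))), 0.5)
  # everything at or below the threshold -> no centroid on this slice
  expect_null(fit_inplane_center(matrix(40, 32, 32)))
  expect_null(fit_inplane_center(matrix(0, 32, 32)))
})

test_that("aggregation recovers phantom centroids to within 2 mm", {
  ph <- small_phantom(n = 5, seed = 17)
  found <- aggregate_centroids(densify_spine(ph$labels, ph$centroids))
  expect_equal(nrow(found), 5)
  expect_identical(found$vertebra_id, 1:5)
  errs <- centroid_errors(found, ph$centroids)
  expect_lt(mean(errs), 2)
  d <- dim(ph$labels$data)
  expect_true(all(found$z >= 0 & found$z < d[1]))
  expect_true(all(found$y >= 0 & found$y < d[2]))
  expect_true(all(found$x >= 0 & found$x < d[3]))
})

test_that("aggregation is translation-equivariant and empty-safe", {
  empty <- aggregate_centroids(array(0, c(30, 20, 20)))
  expect_equal(nrow(empty), 0)

  ph <- generate_spine_phantom(spine_phantom_spec(
    n_vertebrae = 1, body_radius_mm = 9, body_height_mm = 16, seed = 5))
  dense <- densify_spine(ph$labels, ph$centroids)
  base <- aggregate_centroids(dense)
  d <- dim(dense$data)
  shift <- c(4, 3, 2)
  big <- array(0, d + shift)
  big[(shift[1] + 1):(shift[1] + d[1]),
      (shift[2] + 1):(shift[2] + d[2]),
      (shift[3] + 1):(shift[3] + d[3])] <- dense$data
  moved <- aggregate_centroids(big)
  expect_equal(nrow(moved), 1)
  expect_true(all(abs(as.numeric(moved[1, c("z", "y", "x")]) -
                      as.numeric(base[1, c("z", "y", "x")]) - shift) <= 0.5))
})
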