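test_that("network output preserves spatial shape and lies in (0, 1)", {
  net2 <- build_dense_unet(net_config(2, depth = 3, base_filters = 2), seed = 1)
  x <- array(runif(32 * 24 * 9), c(32, 24, 9))
  p <- predict(net2, x)
  expect_equal(dim(p), c(32, 24))
  expect_true(all(p > 0 & p < 1))

  net3 <- build_dense_unet(net_config(3, depth = 3, base_filters = 1), seed = 1)
  x3 <- array(runif(16 * 20 * 12), c(16, 20, 12))
  p3 <- predict(net3, x3)
  expect_equal(dim(p3), c(16, 20, 12))
  expect_true(all(p3 > 0 & p3 < 1))
})

test_that("builds are deterministic and bad sizes are rejected", {
  cfg <- net_config(2, depth = 3, base_filters = 2)
  a <- build_dense_unet(cfg, seed = 3)
  b <- build_dense_unet(cfg, seed = 3)
  expect_identical(a$params, b$params)
  expect_equal(n_parameters(a), n_parameters(b))
  expect_error(predict(a, array(0, c(30, 30, 9))), "divisible")
  expect_error(predict(a, array(0, c(32, 32, 5))), "channels")
  expect_error(net_config(4), "dims")
  expect_error(net_config(2, depth = 1), "invalid")
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(array(0.5, c(2, 2)), array(0.5, c(2, 2))), log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(0.8, 1), -log(0.8), tolerance = 1e-12)
  t <- array(runif(16), c(4, 4))
  expect_lt(bce_loss(pmin(pmax(t, 1e-7), 1 - 1e-7), t), bce_loss(0.5 * t + 0.25, t))
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))  # clipped, not -Inf
  expect_error(bce_loss(c(0.5, 0.5), 0.5), "mismatch")
})

test_that("backpropagated gradients match finite differences", {
  # tiny end-to-end gradient check through conv/relu/pool/upsample/
  # concat/sigmoid and the BCE seed
  cfg <- net_config(2, in_channels = 2, depth = 2, base_filters = 2)
  net <- build_dense_unet(cfg, seed = 11)
  set.seed(12)
  x <- array(runif(6 * 4 * 2), c(6, 4, 2))
  t <- array(runif(6 * 4), c(6, 4))
  loss_of <- function(net) {
    p <- predict(net, x)
    bce_loss(p, t)
  }
  ctx <- spineseg:::tape_new()
  fw <- spineseg:::forward_dense_unet(net, x, ctx)
  p <- fw$out$v
  tt <- t; dim(tt) <- dim(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  grads <- spineseg:::tape_backward(ctx, fw$out$id,
                                    (pc - tt) / (pc * (1 - pc)) / length(p))
  eps <- 1e-6
  set.seed(13)
  for (name in sample(names(net$params), 6)) {
    g_an <- grads[[ctx$param_ids[[name]]]]
    k <- sample(length(net$params[[name]]), 1)
    for (sgn in c(1, -1)) {
      net2 <- net
      net2$params[[name]][k] <- net2$params[[name]][k] + sgn * eps
      assign(if (sgn > 0) "lp" else "lm", loss_of(net2))
    }
    g_fd <- (lp - lm) / (2 * eps)
    expect_equal(as.numeric(g_an[k]), g_fd, tolerance = 1e-4)
  }
})

test_that("training on one sample reduces the loss deterministically", {
  ph <- small_phantom(n = 3, seed = 2)
  dense <- densify_spine(ph$labels)
  z <- round(ph$centroids$z[2])
  stack <- normalize_intensity(build_slice_stack(ph$image, z, 4))[1:48, 1:40, ]
  target <- dense$data[z + 1, 1:48, 1:40] / 255
  net <- build_dense_unet(net_config(2, depth = 3, base_filters = 2), seed = 7)
  tr <- train_dense_unet(net, list(list(x = stack, y = target)),
                         train_config(epochs = 10, seed = 5))
  expect_length(tr$history, 10)
  expect_lt(tr$history[10], tr$history[1])
  # same seed, same device -> identical loss history
  tr2 <- train_dense_unet(net, list(list(x = stack, y = target)),
                          train_config(epochs = 10, seed = 5))
  expect_identical(tr$history, tr2$history)
  expect_error(train_dense_unet(net, list(), train_config()), "empty")
})

test_that("checkpoints round trip through disk", {
  dir <- withr::local_tempdir()
  net <- build_dense_unet(net_config(3, depth = 2, base_filters = 1), seed = 2)
  save_dense_unet(net, file.path(dir, "net.rds"))
  expect_true(file.exists(file.path(dir, "net.rds.json")))
  r <- load_dense_unet(file.path(dir, "net.rds"))
  expect_identical(r$params, net$params)
})
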