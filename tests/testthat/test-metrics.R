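# Exhaustive pairwise-distance oracle for the Hausdorff distance:
# surface voxels found by explicit neighbor loops, distances by brute
# force, fully independent of the package implementation.
hausdorff_oracle <- function(G, P) {
  surf <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in which(m != 0)) {
      z <- (i - 1) %% d[1] + 1
      y <- ((i - 1) %/% d[1]) %% d[2] + 1
      x <- (i - 1) %/% (d[1] * d[2]) + 1
      nb <- rbind(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
                  c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
      is_surface <- FALSE
      for (r in seq_len(6)) {
        q <- nb[r, ]
        if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
          is_surface <- TRUE
          break
        }
      }
      if (is_surface) out <- rbind(out, c(z, y, x))
    }
    out
  }
  sg <- surf(G); sp <- surf(P)
  h <- function(a, b) {
    mx <- 0
    for (i in seq_len(nrow(a))) {
      mn <- Inf
      for (j in seq_len(nrow(b)))
        mn <- min(mn, sqrt(sum((a[i, ] - b[j, ])^2)))
      mx <- max(mx, mn)
    }
    mx
  }
  max(h(sg, sp), h(sp, sg))
}

test_that("location error is the Euclidean distance with id checking", {
  expect_equal(location_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(location_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(location_error(c(0, 0, 0), c(1, 1, 1)), sqrt(3))
  a <- data.frame(vertebra_id = 1, z = 0, y = 0, x = 0)
  b <- data.frame(vertebra_id = 2, z = 3, y = 4, x = 0)
  expect_error(location_error(a, b), "mismatch")
  b$vertebra_id <- 1
  expect_equal(location_error(a, b), 5)
})

test_that("detection rate counts vertebra voxels inside the ROI box", {
  d <- c(40, 40, 40)
  mask <- box_mask(d, c(10, 10, 10), c(19, 19, 19))  # 1000 voxels
  roi_all <- structure(list(data = array(0, c(20, 20, 20)),
                            offset = c(5L, 5L, 5L), size = c(20L, 20L, 20L)),
                       class = "roi_crop")
  expect_equal(detection_rate(mask, roi_all), 100)
  roi_part <- structure(list(offset = c(11L, 10L, 10L),
                             size = c(20L, 20L, 20L)), class = "roi_crop")
  expect_equal(detection_rate(mask, roi_part), 90)
  roi_none <- structure(list(offset = c(30L, 30L, 30L),
                             size = c(5L, 5L, 5L)), class = "roi_crop")
  expect_equal(detection_rate(mask, roi_none), 0)
  expect_error(detection_rate(array(0, d), roi_all), "empty")
})

test_that("Dice and IoU match counting constructions and conventions", {
  d <- c(10, 10, 10)
  X <- box_mask(d, c(0, 0, 0), c(3, 4, 4))        # 100 voxels
  Y <- box_mask(d, c(0, 2, 0), c(3, 6, 4))        # 100 voxels, overlap 60
  di <- dice_iou(X, Y)
  expect_equal(unname(di), c(2 * 60 / 200, 60 / 140), tolerance = 1e-12)
  expect_equal(unname(dice_iou(X, X)), c(1, 1))
  Z <- box_mask(d, c(6, 6, 6), c(8, 8, 8))
  expect_equal(unname(dice_iou(X, Z)), c(0, 0))
  none <- array(FALSE, d)
  expect_equal(unname(dice_iou(none, none)), c(1, 1))
  expect_equal(unname(dice_iou(X, none)), c(0, 0))
  expect_error(dice_iou(X, array(FALSE, c(5, 5, 5))), "mismatch")
})

test_that("IoU = DC / (2 - DC) on random mask pairs", {
  set.seed(51)
  for (i in 1:100) {
    X <- array(runif(512) < 0.4, c(8, 8, 8))
    Y <- array(runif(512) < 0.4, c(8, 8, 8))
    di <- dice_iou(X, Y)
    expect_lt(abs(di[["iou"]] - di[["dice"]] / (2 - di[["dice"]])), 1e-12)
  }
})

test_that("Hausdorff distance matches axioms and the brute-force oracle", {
  d <- c(20, 20, 20)
  G <- box_mask(d, c(2, 2, 2), c(11, 11, 11))
  expect_equal(hausdorff_distance(G, G), 0)
  P <- box_mask(d, c(2, 2, 6), c(11, 11, 15))     # shifted by (0,0,4)
  expect_equal(hausdorff_distance(G, P), 4)
  a <- array(FALSE, d); a[3, 3, 3] <- TRUE
  b <- array(FALSE, d); b[3, 10, 3] <- TRUE
  expect_equal(hausdorff_distance(a, b), 7)
  set.seed(52)
  for (i in 1:3) {
    A <- box_mask(d, s <- sample(0:8, 3, TRUE), s + sample(2:6, 3, TRUE))
    B <- box_mask(d, t <- sample(4:12, 3, TRUE), t + sample(2:6, 3, TRUE))
    expect_equal(hausdorff_distance(A, B), hausdorff_oracle(A, B),
                 tolerance = 1e-12)
    expect_equal(hausdorff_distance(A, B), hausdorff_distance(B, A))
  }
  expect_error(hausdorff_distance(array(FALSE, d), G), "non-empty")
})

test_that("pixel accuracy counts agreeing voxels", {
  d <- c(10, 10, 10)
  G <- box_mask(d, c(0, 0, 0), c(4, 4, 4))
  expect_equal(pixel_accuracy(G, G), 1)
  expect_equal(pixel_accuracy(G, !G), 0)
  P <- G
  P[which(!G)[1:10]] <- TRUE
  expect_equal(pixel_accuracy(G, P), 0.99)
})

test_that("metrics are invariant to a common translation", {
  d <- c(16, 16, 16)
  G <- box_mask(d, c(1, 1, 1), c(6, 6, 6))
  P <- box_mask(d, c(2, 1, 1), c(7, 6, 6))
  G2 <- box_mask(d, c(4, 5, 6), c(9, 10, 11))
  P2 <- box_mask(d, c(5, 5, 6), c(10, 10, 11))
  expect_equal(dice_iou(G, P), dice_iou(G2, P2))
  expect_equal(hausdorff_distance(G, P), hausdorff_distance(G2, P2))
  expect_equal(pixel_accuracy(G, P), pixel_accuracy(G2, P2))
})

test_that("evaluate_spine reports per-vertebra rows and identity aggregates", {
  ph <- small_phantom(n = 3, seed = 25)
  rep <- evaluate_spine(ph$labels, ph$labels,
                        centroids_true = ph$centroids,
                        centroids_pred = ph$centroids)
  expect_equal(nrow(rep$per_vertebra), 3)
  expect_true(all(rep$per_vertebra$DC == 1))
  expect_true(all(rep$per_vertebra$IoU == 1))
  expect_true(all(rep$per_vertebra$HD_mm == 0))
  expect_true(all(rep$per_vertebra$PA == 1))
  expect_true(all(rep$per_vertebra$LE_mm == 0))
  expect_true(all(abs(rep$per_vertebra$IoU -
                      rep$per_vertebra$DC / (2 - rep$per_vertebra$DC)) < 1e-12))
  dir <- withr::local_tempdir()
  write_metrics_report(rep, file.path(dir, "m.csv"))
  expect_true(file.exists(file.path(dir, "m.csv")))
  expect_true(file.exists(file.path(dir, "m.summary.csv")))
})
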