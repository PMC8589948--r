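# Shared fixtures, all generated in code.

small_phantom <- function(n = 3, seed = 1, ...) {
  generate_spine_phantom(spine_phantom_spec(n_vertebrae = n, seed = seed, ...))
}

# Solid ball of the given radius (voxels), centered in a padded cube.
ball_mask <- function(radius, pad = 2) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad  # 0-based center
  g <- (0:(n - 1)) - ctr
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  array(d2 <= radius^2, c(n, n, n))
}

# Axis-aligned solid box mask inside a volume of dims d;
# lo/hi are 0-based inclusive corners.
box_mask <- function(d, lo, hi) {
  m <- array(FALSE, d)
  m[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- TRUE
  m
}

n_components <- function(mask, connectivity = 26) {
  lab <- spineseg:::cpp_label_components(
    array(as.integer(mask != 0), dim(mask)), as.integer(connectivity))
  max(lab)
}

# Exhaustive pairwise-distance Hausdorff oracle for small grids
# (independent loops; no shared code with the implementation).
hausdorff_oracle_small <- function(G, P) {
  surf <- function(m) {
    d <- dim(m)
    keep <- NULL
    idx <- which(m != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      on_surface <- FALSE
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- v
        q[ax] <- q[ax] + s
        if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
          on_surface <- TRUE
        }
      }
      if (on_surface) keep <- rbind(keep, v)
    }
    keep
  }
  a <- surf(G)
  b <- surf(P)
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
  max(h(a, b), h(b, a))
}

centroid_errors <- function(found, truth) {
  stopifnot(nrow(found) == nrow(truth))
  sqrt(rowSums((as.matrix(found[, c("z", "y", "x")]) -
                as.matrix(truth[, c("z", "y", "x")]))^2))
}
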