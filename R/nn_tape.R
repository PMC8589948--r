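# Minimal reverse-mode autodiff tape used by the Dense-U-Net.  Tensors
# are R arrays (z, y, x, channel); the heavy kernels (convolution, max
# pooling) live in compiled code, the remaining ops are vectorized R.
# With ctx = NULL every op runs in plain inference mode and records
# nothing.

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$vals <- list()
  e$parents <- list()
  e$backward <- list()
  e$param_ids <- list()
  e
}

tape_node <- function(ctx, value, parents = list(), backward = NULL) {
  if (is.null(ctx)) return(list(v = value, id = NA_integer_))
  ctx$n <- ctx$n + 1L
  ctx$vals[[ctx$n]] <- TRUE  # values live in the op closures; flag only
  ctx$parents[[ctx$n]] <- vapply(parents, `[[`, integer(1), "id")
  ctx$backward[[ctx$n]] <- backward
  list(v = value, id = ctx$n)
}

tape_param <- function(ctx, net, name) {
  nd <- tape_node(ctx, net$params[[name]])
  if (!is.null(ctx)) ctx$param_ids[[name]] <- nd$id
  nd
}

op_conv <- function(ctx, x, w, b) {
  y <- cpp_conv_fwd(x$v, w$v, b$v)
  xv <- x$v; wv <- w$v
  tape_node(ctx, y, list(x, w, b), function(g) {
    r <- cpp_conv_bwd(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

op_relu <- function(ctx, x) {
  y <- x$v
  y[y < 0] <- 0
  mask <- x$v > 0
  tape_node(ctx, y, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(ctx, x) {
  y <- 1 / (1 + exp(-x$v))
  tape_node(ctx, y, list(x), function(g) list(g * y * (1 - y)))
}

op_maxpool <- function(ctx, x, pool) {
  r <- cpp_maxpool_fwd(x$v, pool[1], pool[2], pool[3])
  xdim <- dim(x$v)
  tape_node(ctx, r$y, list(x), function(g) {
    list(cpp_maxpool_bwd(r$idx, g, as.integer(xdim)))
  })
}

op_upsample <- function(ctx, x, pool) {
  d <- dim(x$v)
  y <- x$v[rep(seq_len(d[1]), each = pool[1]),
           rep(seq_len(d[2]), each = pool[2]),
           rep(seq_len(d[3]), each = pool[3]), , drop = FALSE]
  tape_node(ctx, y, list(x), function(g) {
    gx <- array(0, d)
    for (dz in seq_len(pool[1]))
      for (dy in seq_len(pool[2]))
        for (dx in seq_len(pool[3]))
          gx <- gx + g[seq(dz, by = pool[1], length.out = d[1]),
                       seq(dy, by = pool[2], length.out = d[2]),
                       seq(dx, by = pool[3], length.out = d[3]), , drop = FALSE]
    list(gx)
  })
}

op_concat <- function(ctx, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(all(da[1:3] == db[1:3]))
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a$v
  y[, , , da[4] + seq_len(db[4])] <- b$v
  tape_node(ctx, y, list(a, b), function(g) {
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# Accumulates gradients in reverse creation order; returns the list of
# per-node gradients (indexed by node id).
tape_backward <- function(ctx, out_id, seed_grad) {
  grads <- vector("list", ctx$n)
  grads[[out_id]] <- seed_grad
  for (i in seq.int(ctx$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(ctx$backward[[i]])) next
    pg <- ctx$backward[[i]](g)
    ps <- ctx$parents[[i]]
    for (j in seq_along(ps)) {
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[i] <- list(NULL)  # free
  }
  grads
}
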