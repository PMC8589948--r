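# Dense-U-Net: a U-shaped encoder-decoder in which every resolution
# block carries two extra interconnections on top of the usual U-Net
# skips -- a dense interconnection that concatenates the unprocessed
# block input onto the second convolution's input, and a residual
# interconnection that concatenates the block input onto the block
# output.  Both are realized as channel concatenation.  The 2D variant
# (vertebra localization from 2k+1 transversal slices as channels) and
# the 3D variant (vertebra segmentation in an ROI) share one
# implementation; 2D runs with a singleton z axis.

#' Dense-U-Net architecture configuration
#'
#' @param dims 2 (localization net, slice channels) or 3 (segmentation
#'   net).
#' @param in_channels input channels; defaults to 9 (= 2k+1 slices with
#'   k = 4) in 2D and 1 in 3D.
#' @param depth number of resolution levels (>= 2); inputs must be
#'   divisible by `2^(depth - 1)` along each pooled axis.
#' @param base_filters filters of the first level; doubled per level.
#' @param kernel odd convolution kernel size.
#' @return A `net_config` list.
#' @export
net_config <- function(dims, in_channels = NULL, depth = 5, base_filters = 32,
                       kernel = 3) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (is.null(in_channels)) in_channels <- if (dims == 2L) 9L else 1L
  if (depth < 2 || base_filters < 1 || in_channels < 1)
    stop("invalid network configuration")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  structure(list(dims = dims, in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel)),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults follow the standard Adam setup used for both networks:
#' batch size 1, learning rate 1e-5, beta1 0.9, beta2 0.999, epsilon
#' 1e-8, learning-rate decay 1.99e-7 per step; 30 epochs for the 2D net
#' and 50 for the 3D net.
#'
#' @param batch_size must be 1.
#' @param lr,beta1,beta2,epsilon,decay Adam hyperparameters.
#' @param epochs training epochs.
#' @param seed RNG seed for reproducible runs.
#' @export
train_config <- function(batch_size = 1, lr = 1e-5, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, decay = 1.99e-7,
                         epochs = 30, seed = 1) {
  if (batch_size != 1) stop("batch_size is fixed to 1")
  if (lr <= 0 || epsilon <= 0 || epochs < 1) stop("invalid training config")
  structure(list(batch_size = 1L, lr = lr, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, decay = decay,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Build a Dense-U-Net
#'
#' Constructs the parameter set for the configured network: per level
#' two `kernel`-sized convolutions with ReLU, 2x max pooling on the way
#' down and 2x nearest-neighbor upsampling on the way up, dense and
#' residual concatenations inside each block, U-Net skips between
#' equal-resolution encoder and decoder blocks, and a final 1x1
#' convolution with sigmoid so the output lies in (0, 1).  Weights use
#' He-normal initialization from `seed`; builds are deterministic.
#'
#' @param cfg a [net_config()].
#' @param seed initialization seed.
#' @return A `dense_unet` object.
#' @export
build_dense_unet <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(seed)
  k <- cfg$kernel
  kdim <- if (cfg$dims == 2L) c(1L, k, k) else c(k, k, k)
  params <- list()
  add_conv <- function(name, cin, cout, kd = kdim) {
    fan_in <- prod(kd) * cin
    params[[paste0(name, "_w")]] <<-
      array(rnorm(prod(kd) * cin * cout, 0, sqrt(2 / fan_in)), c(kd, cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_block <- function(name, cin, f) {
    add_conv(paste0(name, "_conv1"), cin, f)
    add_conv(paste0(name, "_conv2"), cin + f, f)
    cin + f  # residual concatenation of the block input
  }
  cin <- cfg$in_channels
  enc_out <- integer(cfg$depth - 1L)
  for (l in seq_len(cfg$depth - 1L)) {
    cin <- add_block(sprintf("enc%d", l), cin, cfg$base_filters * 2^(l - 1))
    enc_out[l] <- cin
  }
  cur <- add_block("bott", cin, cfg$base_filters * 2^(cfg$depth - 1))
  for (l in seq.int(cfg$depth - 1L, 1L)) {
    cur <- add_block(sprintf("dec%d", l), cur + enc_out[l],
                     cfg$base_filters * 2^(l - 1))
  }
  add_conv("final", cur, 1L, kd = c(1L, 1L, 1L))
  structure(list(cfg = cfg, params = params, enc_out = enc_out),
            class = "dense_unet")
}

#' @export
print.dense_unet <- function(x, ...) {
  cat(sprintf("<dense_unet> %dD, depth %d, base filters %d, %s parameters\n",
              x$cfg$dims, x$cfg$depth, x$cfg$base_filters,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `dense_unet`.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, numeric(1)))

.as_net_input <- function(net, x) {
  cfg <- net$cfg
  d <- dim(x)
  if (cfg$dims == 2L) {
    if (length(d) == 2L) dim(x) <- c(1L, d, 1L)
    else if (length(d) == 3L) dim(x) <- c(1L, d)   # (H, W, C)
    else stop("2D network input must be (H, W) or (H, W, channels)")
  } else {
    if (length(d) == 3L) dim(x) <- c(d, 1L)
    else if (length(d) != 4L) stop("3D network input must be (Z, Y, X[, C])")
  }
  d <- dim(x)
  if (d[4] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[4]))
  div <- 2^(cfg$depth - 1L)
  pooled <- if (cfg$dims == 2L) d[2:3] else d[1:3]
  if (any(pooled %% div != 0))
    stop(sprintf("input spatial size (%s) must be divisible by %d",
                 paste(pooled, collapse = "x"), div))
  x
}

forward_dense_unet <- function(net, x, ctx = NULL) {
  cfg <- net$cfg
  x <- .as_net_input(net, x)
  pool <- if (cfg$dims == 2L) c(1L, 2L, 2L) else c(2L, 2L, 2L)
  P <- function(name) tape_param(ctx, net, name)
  block <- function(inp, name) {
    h1 <- op_relu(ctx, op_conv(ctx, inp, P(paste0(name, "_conv1_w")),
                               P(paste0(name, "_conv1_b"))))
    h1 <- op_concat(ctx, inp, h1)  # dense interconnection
    h2 <- op_relu(ctx, op_conv(ctx, h1, P(paste0(name, "_conv2_w")),
                               P(paste0(name, "_conv2_b"))))
    op_concat(ctx, h2, inp)        # residual interconnection
  }
  cur <- tape_node(ctx, x)
  skips <- vector("list", cfg$depth - 1L)
  for (l in seq_len(cfg$depth - 1L)) {
    cur <- block(cur, sprintf("enc%d", l))
    skips[[l]] <- cur
    cur <- op_maxpool(ctx, cur, pool)
  }
  cur <- block(cur, "bott")
  for (l in seq.int(cfg$depth - 1L, 1L)) {
    cur <- op_upsample(ctx, cur, pool)
    cur <- op_concat(ctx, cur, skips[[l]])
    cur <- block(cur, sprintf("dec%d", l))
  }
  out <- op_sigmoid(ctx, op_conv(ctx, cur, P("final_w"), P("final_b")))
  list(out = out, ctx = ctx)
}

#' Forward pass of a Dense-U-Net
#'
#' @param object a `dense_unet`.
#' @param x input: `(H, W)` matrix or `(H, W, channels)` array for the
#'   2D net, `(Z, Y, X[, C])` array for the 3D net.
#' @param ... unused.
#' @return Sigmoid output in (0, 1) with the input's spatial shape:
#'   an `(H, W)` matrix (2D) or `(Z, Y, X)` array (3D).
#' @export
predict.dense_unet <- function(object, x, ...) {
  v <- forward_dense_unet(object, x, NULL)$out$v
  if (object$cfg$dims == 2L) v[1, , , 1] else v[, , , 1]
}

#' Binary cross-entropy
#'
#' Mean of `-(t log p + (1 - t) log(1 - p))`; predictions are clipped to
#' `[eps, 1 - eps]` so the loss is always finite.
#'
#' @param pred predictions in (0, 1).
#' @param target targets in `[0, 1]`, same shape.
#' @param eps clipping constant.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (length(pred) != length(target)) stop("pred/target shape mismatch")
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Train a Dense-U-Net
#'
#' Plain stochastic training at batch size 1 with Adam (step-wise
#' learning-rate decay `lr / (1 + decay * step)`), minimizing binary
#' cross-entropy.  Runs are reproducible for a fixed seed on the same
#' machine.
#'
#' @param net a `dense_unet` from [build_dense_unet()].
#' @param dataset non-empty list of `list(x = input, y = target)` pairs;
#'   targets in `[0, 1]` with the input's spatial shape.
#' @param cfg a [train_config()].
#' @return List with the trained `net` and `history`, the per-epoch mean
#'   training loss.
#' @export
train_dense_unet <- function(net, dataset, cfg = train_config()) {
  stopifnot(inherits(net, "dense_unet"), inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("training dataset is empty")
  set.seed(cfg$seed)
  m <- lapply(net$params, function(p) array(0, dim = dim(p) %||% length(p)))
  v <- lapply(net$params, function(p) array(0, dim = dim(p) %||% length(p)))
  step <- 0L
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    losses <- numeric(length(dataset))
    for (s in seq_along(dataset)) {
      ctx <- tape_new()
      fw <- forward_dense_unet(net, dataset[[s]]$x, ctx)
      p <- fw$out$v
      t <- dataset[[s]]$y
      dim(t) <- dim(p)
      loss <- bce_loss(p, t)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, sample %d", epoch, s))
      losses[s] <- loss
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      seed_grad <- (pc - t) / (pc * (1 - pc)) / length(p)
      grads <- tape_backward(ctx, fw$out$id, seed_grad)
      step <- step + 1L
      lr_t <- cfg$lr / (1 + cfg$decay * step)
      for (name in names(net$params)) {
        id <- ctx$param_ids[[name]]
        g <- grads[[id]]
        if (is.null(g)) next
        m[[name]] <- cfg$beta1 * m[[name]] + (1 - cfg$beta1) * g
        v[[name]] <- cfg$beta2 * v[[name]] + (1 - cfg$beta2) * g^2
        mh <- m[[name]] / (1 - cfg$beta1^step)
        vh <- v[[name]] / (1 - cfg$beta2^step)
        net$params[[name]] <- net$params[[name]] -
          lr_t * mh / (sqrt(vh) + cfg$epsilon)
      }
    }
    history[epoch] <- mean(losses)
  }
  list(net = net, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file; the architecture configuration is also
#' serialized as JSON next to it for inspection.
#'
#' @param net a `dense_unet`.
#' @param path checkpoint path.
#' @export
save_dense_unet <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dense_unet
#' @export
load_dense_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "dense_unet"))
  net
}
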