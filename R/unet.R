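# The 1-D U-Net mapping a one-hot context window to an (n+1)-class
# probability vector for a single junction.
#
# Encoder: a stride-1 stem (the first entry of the stride list) followed by
# five dimensionality-expansion stages; each stage is a strided convolution,
# batch normalization, ReLU and a ResNet-style residual block. Channels grow
# linearly (c0, 2c0, ..., 5c0). Decoder: transposed-convolution upsampling
# mirrored on the same stride list, concatenating the spatially matched
# encoder feature map at each level, then a convolution to fuse. Head: a
# 1x1 convolution collapsing channels, flatten, one hidden fully connected
# layer, then n+1 logits.

#' Create and validate a model configuration
#'
#' @param L input window length (even; the stride product must divide it).
#' @param stride_list six integers; the first must be 1 (the stem), the
#'   remaining five are the stage strides.
#' @param c0 first-layer channel count; stage channels are c0, 2c0, ... 5c0.
#' @param kernel_size odd convolution kernel width.
#' @param n_classes number of INDEL length classes n (output has n+1 slots).
#' @param fc_width hidden fully connected layer width.
#' @param head_crop number of central columns of the full-resolution decoder
#'   map fed to the fully connected head (the prediction is focal: distal
#'   context reaches the head through the encoder-decoder path, while the
#'   head itself reads the junction-centred columns).
#' @return a validated `model_config` with derived `channels` and
#'   `bottleneck_length`.
#' @export
model_config <- function(L = 8000L, stride_list = c(1L, 4L, 5L, 5L, 5L, 4L),
                         c0 = 8L, kernel_size = 5L, n_classes = 7L,
                         fc_width = 64L, head_crop = 64L) {
  L <- as.integer(L); stride_list <- as.integer(stride_list)
  head_crop <- as.integer(min(head_crop, L))
  if (head_crop < 2L || head_crop %% 2L != 0L) stop("head_crop must be even and >= 2")
  if (L %% 2L != 0L || L < 2L) stop("L must be even and >= 2")
  if (length(stride_list) != 6L) stop("stride_list must have 6 entries")
  if (stride_list[1L] != 1L) stop("first stride must be 1")
  if (any(stride_list < 1L)) stop("strides must be >= 1")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  prod_s <- prod(stride_list)
  if (L %% prod_s != 0L) stop("product of strides must divide L")
  bottleneck <- L %/% prod_s
  if (bottleneck < 1L) stop("bottleneck length < 1")
  structure(list(L = L, stride_list = stride_list, c0 = as.integer(c0),
                 kernel_size = as.integer(kernel_size),
                 n_classes = as.integer(n_classes),
                 fc_width = as.integer(fc_width),
                 head_crop = head_crop,
                 channels = as.integer(c0 * 1:5),
                 bottleneck_length = as.integer(bottleneck)),
            class = "model_config")
}

#' @rdname model_config
#' @param cfg a list with the `model_config` fields.
#' @export
validate_config <- function(cfg) {
  flds <- c("L", "stride_list", "c0", "kernel_size", "n_classes",
            "fc_width", "head_crop")
  if (is.null(cfg$head_crop)) flds <- setdiff(flds, "head_crop")
  do.call(model_config, cfg[flds])
}

stage_channels <- function(cfg) c(cfg$c0, cfg$channels)  # stem + 5 stages

stage_lengths <- function(cfg) {
  # length entering each of stem, stage1..5, and the bottleneck length
  s <- cfg$stride_list
  lens <- integer(7L)
  lens[1L] <- cfg$L
  cur <- cfg$L
  for (i in 1:6) {
    cur <- cur %/% s[i]
    lens[i + 1L] <- cur
  }
  lens
}

#' Initialize a model
#'
#' He-initialized weights; batchnorm gamma 1, beta 0. Deterministic given
#' the seed.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed.
#' @return a `unet_model`: list with `cfg`, `params` (named list of arrays)
#'   and `bn` (running-statistics environment).
#' @export
init_model <- function(cfg, seed = 1L) {
  cfg <- validate_config(cfg)
  set.seed(seed)
  K <- cfg$kernel_size
  ch <- stage_channels(cfg)          # c0, c0, 2c0, 3c0, 4c0, 5c0
  p <- list()
  bn_keys <- character()
  add_conv <- function(p, nm, cout, cin, k) {
    p[[paste0(nm, "_W")]] <- he_init(c(cout, cin, k), cin * k)
    p[[paste0(nm, "_b")]] <- numeric(cout)
    p
  }
  add_bn <- function(p, nm, c) {
    p[[paste0(nm, "_g")]] <- rep(1, c)
    p[[paste0(nm, "_be")]] <- numeric(c)
    bn_keys <<- c(bn_keys, nm)
    p
  }
  add_res <- function(p, prefix, c) {
    p <- add_conv(p, paste0(prefix, "_conv1"), c, c, K)
    p <- add_bn(p, paste0(prefix, "_bn1"), c)
    p <- add_conv(p, paste0(prefix, "_conv2"), c, c, K)
    add_bn(p, paste0(prefix, "_bn2"), c)
  }
  # stem (stride 1)
  p <- add_conv(p, "stem_conv", ch[1L], 4L, K)
  p <- add_bn(p, "stem_bn", ch[1L])
  p <- add_res(p, "stem_res", ch[1L])
  # encoder stages
  for (i in 1:5) {
    pre <- paste0("enc", i)
    p <- add_conv(p, paste0(pre, "_down"), ch[i + 1L], ch[i], K)
    p <- add_bn(p, paste0(pre, "_bn"), ch[i + 1L])
    p <- add_res(p, paste0(pre, "_res"), ch[i + 1L])
  }
  # decoder stages (5 -> 1)
  for (i in 5:1) {
    pre <- paste0("dec", i)
    s <- cfg$stride_list[i + 1L]
    p[[paste0(pre, "_up_W")]] <- he_init(c(ch[i], ch[i + 1L], s), ch[i + 1L])
    p[[paste0(pre, "_up_b")]] <- numeric(ch[i])
    p <- add_bn(p, paste0(pre, "_upbn"), ch[i])
    p <- add_conv(p, paste0(pre, "_fuse"), ch[i], 2L * ch[i], K)
    p <- add_bn(p, paste0(pre, "_bn"), ch[i])
  }
  # head
  p <- add_conv(p, "head_conv", 1L, ch[1L], 1L)
  p[["head_fc1_W"]] <- he_init(c(cfg$fc_width, cfg$head_crop), cfg$head_crop)
  p[["head_fc1_b"]] <- numeric(cfg$fc_width)
  p[["head_fc2_W"]] <- he_init(c(cfg$n_classes + 1L, cfg$fc_width),
                               cfg$fc_width)
  p[["head_fc2_b"]] <- numeric(cfg$n_classes + 1L)
  bn <- new.env(parent = emptyenv())
  for (k in bn_keys) {
    cdim <- length(p[[paste0(k, "_g")]])
    bn[[k]] <- list(mean = numeric(cdim), var = rep(1, cdim))
  }
  structure(list(cfg = cfg, params = p, bn = bn, seed = as.integer(seed)),
            class = "unet_model")
}

#' Count trainable parameters
#' @param model a `unet_model` or a [model_config()].
#' @return integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_config")) model <- init_model(model, seed = 0L)
  sum(vapply(model$params, length, 0L))
}

conv_bn_relu_f <- function(p, bn, nm_conv, nm_bn, X, stride, pad, train) {
  c1 <- conv1d_forward(X, p[[paste0(nm_conv, "_W")]],
                       p[[paste0(nm_conv, "_b")]], stride, pad)
  b1 <- bnrelu_forward(c1$out, p[[paste0(nm_bn, "_g")]],
                       p[[paste0(nm_bn, "_be")]], bn, nm_bn, train)
  list(out = b1$out, cache = list(conv = c1$cache, bn = b1$cache))
}

conv_bn_relu_b <- function(p, g, nm_conv, nm_bn, dY, cache) {
  bb <- bnrelu_backward(dY, p[[paste0(nm_bn, "_g")]], cache$bn)
  g[[paste0(nm_bn, "_g")]] <- bb$dgamma
  g[[paste0(nm_bn, "_be")]] <- bb$dbeta
  cb <- conv1d_backward(bb$dX, p[[paste0(nm_conv, "_W")]], cache$conv)
  g[[paste0(nm_conv, "_W")]] <- cb$dW
  g[[paste0(nm_conv, "_b")]] <- cb$db
  list(dX = cb$dX, g = g)
}

res_block_f <- function(p, bn, prefix, X, pad, train) {
  a <- conv_bn_relu_f(p, bn, paste0(prefix, "_conv1"), paste0(prefix, "_bn1"),
                      X, 1L, pad, train)
  c2 <- conv1d_forward(a$out, p[[paste0(prefix, "_conv2_W")]],
                       p[[paste0(prefix, "_conv2_b")]], 1L, pad)
  b2 <- bn_forward(c2$out, p[[paste0(prefix, "_bn2_g")]],
                   p[[paste0(prefix, "_bn2_be")]], bn,
                   paste0(prefix, "_bn2"), train)
  out <- add_relu_fwd_cpp(b2$out, X)
  list(out = out, cache = list(a = a$cache, conv2 = c2$cache,
                               bn2 = b2$cache, relu = out))
}

res_block_b <- function(p, g, prefix, dY, cache) {
  dsum <- relu_backward(dY, cache$relu)
  bb <- bn_backward(dsum, p[[paste0(prefix, "_bn2_g")]], cache$bn2)
  g[[paste0(prefix, "_bn2_g")]] <- bb$dgamma
  g[[paste0(prefix, "_bn2_be")]] <- bb$dbeta
  cb <- conv1d_backward(bb$dX, p[[paste0(prefix, "_conv2_W")]], cache$conv2)
  g[[paste0(prefix, "_conv2_W")]] <- cb$dW
  g[[paste0(prefix, "_conv2_b")]] <- cb$db
  r1 <- conv_bn_relu_b(p, g, paste0(prefix, "_conv1"), paste0(prefix, "_bn1"),
                       cb$dX, cache$a)
  list(dX = r1$dX + dsum, g = r1$g)
}

#' Forward pass
#'
#' @param model a `unet_model`.
#' @param X one-hot batch, array (4, L, B) (a single 4xL matrix is accepted).
#' @param train logical; training mode uses batch statistics in batchnorm
#'   and records caches for backprop.
#' @return list with `probs` ((n+1) x B column-stochastic matrix), `logits`,
#'   and (when `train` or `keep_cache`) `cache` for [unet_backward()].
#' @param keep_cache record caches even in eval mode (for attribution).
#' @export
unet_forward <- function(model, X, train = FALSE, keep_cache = train) {
  cfg <- model$cfg; p <- model$params; bn <- model$bn
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  stopifnot(dim(X)[1L] == 4L, dim(X)[2L] == cfg$L)
  pad <- (cfg$kernel_size - 1L) %/% 2L
  caches <- list()
  # stem
  st <- conv_bn_relu_f(p, bn, "stem_conv", "stem_bn", X, 1L, pad, train)
  caches$stem <- st$cache
  sr <- res_block_f(p, bn, "stem_res", st$out, pad, train)
  caches$stem_res <- sr$cache
  skips <- list(sr$out)  # encoder outputs entering each decoder concat
  cur <- sr$out
  for (i in 1:5) {
    pre <- paste0("enc", i)
    dn <- conv_bn_relu_f(p, bn, paste0(pre, "_down"), paste0(pre, "_bn"),
                         cur, cfg$stride_list[i + 1L], pad, train)
    caches[[paste0(pre, "_down")]] <- dn$cache
    rb <- res_block_f(p, bn, paste0(pre, "_res"), dn$out, pad, train)
    caches[[paste0(pre, "_res")]] <- rb$cache
    cur <- rb$out
    if (i < 5L) skips[[i + 1L]] <- cur
  }
  for (i in 5:1) {
    pre <- paste0("dec", i)
    s <- cfg$stride_list[i + 1L]
    up <- convt1d_forward(cur, p[[paste0(pre, "_up_W")]],
                          p[[paste0(pre, "_up_b")]], s)
    caches[[paste0(pre, "_up")]] <- up$cache
    ub <- bnrelu_forward(up$out, p[[paste0(pre, "_upbn_g")]],
                         p[[paste0(pre, "_upbn_be")]], bn,
                         paste0(pre, "_upbn"), train)
    caches[[paste0(pre, "_upbn")]] <- ub$cache
    ur <- ub
    skip <- skips[[i]]
    cat_in <- array(0, c(dim(ur$out)[1L] * 2L, dim(ur$out)[2L], dim(ur$out)[3L]))
    cc <- dim(ur$out)[1L]
    cat_in[seq_len(cc), , ] <- ur$out
    cat_in[cc + seq_len(cc), , ] <- skip
    fz <- conv_bn_relu_f(p, bn, paste0(pre, "_fuse"), paste0(pre, "_bn"),
                         cat_in, 1L, pad, train)
    caches[[paste0(pre, "_fuse")]] <- fz$cache
    cur <- fz$out
  }
  hc <- conv1d_forward(cur, p$head_conv_W, p$head_conv_b, 1L, 0L)
  caches$head_conv <- hc$cache
  B <- dim(X)[3L]
  crop <- (cfg$L - cfg$head_crop) %/% 2L
  crop_cols <- (crop + 1L):(crop + cfg$head_crop)
  flat <- matrix(hc$out[, crop_cols, , drop = FALSE], cfg$head_crop, B)
  f1 <- dense_forward(flat, p$head_fc1_W, p$head_fc1_b)
  caches$head_fc1 <- f1$cache
  f1r <- relu_forward(f1$out)
  caches$head_fc1_relu <- f1r$cache
  f2 <- dense_forward(f1r$out, p$head_fc2_W, p$head_fc2_b)
  caches$head_fc2 <- f2$cache
  logits <- f2$out
  if (any(!is.finite(logits))) stop("non-finite activations in forward pass")
  list(probs = softmax_cols(logits), logits = logits,
       cache = if (keep_cache) caches else NULL, B = B)
}

#' Backward pass
#'
#' Propagates a gradient on the logits back through the network, returning
#' parameter gradients and the gradient with respect to the input window.
#'
#' @param model a `unet_model`.
#' @param fwd result of [unet_forward()] with a cache.
#' @param dlogits (n+1) x B gradient on the logits.
#' @return list with `grads` (named like `model$params`) and `dX`
#'   (4, L, B array).
#' @export
unet_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params
  caches <- fwd$cache
  if (is.null(caches)) stop("forward pass was run without cache")
  g <- list()
  f2 <- dense_backward(dlogits, p$head_fc2_W, caches$head_fc2)
  g$head_fc2_W <- f2$dW; g$head_fc2_b <- f2$db
  d1 <- relu_backward(f2$dX, caches$head_fc1_relu)
  f1 <- dense_backward(d1, p$head_fc1_W, caches$head_fc1)
  g$head_fc1_W <- f1$dW; g$head_fc1_b <- f1$db
  B <- fwd$B
  crop <- (cfg$L - cfg$head_crop) %/% 2L
  dhead <- array(0, c(1L, cfg$L, B))
  dhead[, (crop + 1L):(crop + cfg$head_crop), ] <- f1$dX
  hc <- conv1d_backward(dhead, p$head_conv_W, caches$head_conv)
  g$head_conv_W <- hc$dW; g$head_conv_b <- hc$db
  dcur <- hc$dX
  pad <- (cfg$kernel_size - 1L) %/% 2L
  dskips <- vector("list", 5L)
  for (i in 1:5) {
    pre <- paste0("dec", i)
    fb <- conv_bn_relu_b(p, g, paste0(pre, "_fuse"), paste0(pre, "_bn"),
                         dcur, caches[[paste0(pre, "_fuse")]])
    g <- fb$g
    cc <- dim(fb$dX)[1L] %/% 2L
    dup <- fb$dX[seq_len(cc), , , drop = FALSE]
    dskips[[i]] <- fb$dX[cc + seq_len(cc), , , drop = FALSE]
    ub <- bnrelu_backward(dup, p[[paste0(pre, "_upbn_g")]],
                          caches[[paste0(pre, "_upbn")]])
    g[[paste0(pre, "_upbn_g")]] <- ub$dgamma
    g[[paste0(pre, "_upbn_be")]] <- ub$dbeta
    utb <- convt1d_backward(ub$dX, p[[paste0(pre, "_up_W")]],
                            caches[[paste0(pre, "_up")]])
    g[[paste0(pre, "_up_W")]] <- utb$dW
    g[[paste0(pre, "_up_b")]] <- utb$db
    dcur <- utb$dX
  }
  # dcur now sits at the encoder bottleneck (output of enc5_res)
  for (i in 5:1) {
    pre <- paste0("enc", i)
    if (i < 5L) dcur <- dcur + dskips[[i + 1L]]
    rb <- res_block_b(p, g, paste0(pre, "_res"), dcur,
                      caches[[paste0(pre, "_res")]])
    g <- rb$g
    dn <- conv_bn_relu_b(p, g, paste0(pre, "_down"), paste0(pre, "_bn"),
                         rb$dX, caches[[paste0(pre, "_down")]])
    g <- dn$g
    dcur <- dn$dX
  }
  dcur <- dcur + dskips[[1L]]
  sr <- res_block_b(p, g, "stem_res", dcur, caches$stem_res)
  g <- sr$g
  st <- conv_bn_relu_b(p, g, "stem_conv", "stem_bn", sr$dX, caches$stem)
  list(grads = st$g, dX = st$dX)
}

#' Predict probabilities for a batch of windows
#' @param model a `unet_model`.
#' @param X array (4, L, B) or 4xL matrix.
#' @return (n+1) x B matrix of class probabilities (rows: class 0..n).
#' @export
predict_batch <- function(model, X) {
  unet_forward(model, X, train = FALSE, keep_cache = FALSE)$probs
}

#' Initialize a model's weights from a checkpoint (transfer learning)
#'
#' All weights and batchnorm statistics are copied; every layer remains
#' trainable. Any architecture difference is an error.
#'
#' @param cfg target [model_config()].
#' @param checkpoint a `unet_model` or checkpoint list with `cfg`/`params`.
#' @return a `unet_model` with copied weights.
#' @export
init_from_checkpoint <- function(cfg, checkpoint) {
  cfg <- validate_config(cfg)
  src_cfg <- validate_config(checkpoint$cfg)
  for (f in c("L", "stride_list", "c0", "kernel_size", "n_classes",
              "fc_width", "head_crop")) {
    if (!identical(cfg[[f]], src_cfg[[f]])) {
      stop("architecture mismatch on '", f, "'")
    }
  }
  bn <- new.env(parent = emptyenv())
  for (k in ls(checkpoint$bn)) bn[[k]] <- checkpoint$bn[[k]]
  structure(list(cfg = cfg, params = checkpoint$params, bn = bn,
                 seed = checkpoint$seed),
            class = "unet_model")
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture config (also as JSON text) and the
#' training seed; loading onto a mismatched config refuses.
#'
#' @param model a `unet_model`.
#' @param path file path (RDS container).
#' @export
save_checkpoint <- function(model, path) {
  bn_snapshot <- as.list(model$bn)
  obj <- list(cfg = unclass(model$cfg), params = model$params,
              bn = bn_snapshot, seed = model$seed,
              cfg_json = jsonlite::toJSON(unclass(model$cfg), auto_unbox = TRUE),
              val_loss = model$val_loss)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_cfg optional [model_config()]; loading fails on mismatch.
#' @export
load_checkpoint <- function(path, expected_cfg = NULL) {
  obj <- readRDS(path)
  cfg <- validate_config(obj$cfg)
  if (!is.null(expected_cfg) &&
      !identical(unclass(validate_config(expected_cfg)), unclass(cfg))) {
    stop("checkpoint config mismatch")
  }
  bn <- new.env(parent = emptyenv())
  for (k in names(obj$bn)) bn[[k]] <- obj$bn[[k]]
  m <- structure(list(cfg = cfg, params = obj$params, bn = bn,
                      seed = obj$seed),
                 class = "unet_model")
  m$val_loss <- obj$val_loss
  m
}
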