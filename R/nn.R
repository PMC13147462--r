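# Low-level neural-net primitives for 1-D sequence models.
#
# Tensors are numeric arrays of dim (channels, length, batch); the heavy
# kernels (convolution, transposed convolution, batch normalization) are
# compiled (src/layers.cpp, im2col + BLAS GEMM). Each forward returns the output plus a cache
# consumed by the matching backward.

conv1d_forward <- function(X, W, b, stride = 1L, pad = 0L) {
  out <- conv1d_fwd_cpp(X, W, b, stride, pad)
  list(out = out, cache = list(X = X, stride = stride, pad = pad))
}

conv1d_backward <- function(dY, W, cache) {
  conv1d_bwd_cpp(dY, cache$X, W, cache$stride, cache$pad)
}

# Transposed convolution with kernel == stride (exact, non-overlapping
# upsampling: Lout = Lin * stride).
convt1d_forward <- function(X, W, b, stride) {
  list(out = convt1d_fwd_cpp(X, W, b, stride),
       cache = list(X = X, stride = stride))
}

convt1d_backward <- function(dY, W, cache) {
  convt1d_bwd_cpp(dY, cache$X, W, cache$stride)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(X, gamma, beta, state, key, train) {
  st <- state[[key]]
  res <- bn_fwd_cpp(X, gamma, beta, train, st$mean, st$var,
                    BN_MOMENTUM, BN_EPS)
  if (train) state[[key]] <- list(mean = as.numeric(res$new_mean),
                                  var = as.numeric(res$new_var))
  list(out = res$out,
       cache = list(xhat = res$xhat, inv = as.numeric(res$inv),
                    train = train))
}

bnrelu_forward <- function(X, gamma, beta, state, key, train) {
  st <- state[[key]]
  res <- bnrelu_fwd_cpp(X, gamma, beta, train, st$mean, st$var,
                        BN_MOMENTUM, BN_EPS)
  if (train) state[[key]] <- list(mean = as.numeric(res$new_mean),
                                  var = as.numeric(res$new_var))
  list(out = res$out,
       cache = list(out = res$out, xhat = res$xhat,
                    inv = as.numeric(res$inv), train = train))
}

bnrelu_backward <- function(dY, gamma, cache) {
  res <- bnrelu_bwd_cpp(dY, cache$out,
                        if (cache$train) cache$xhat else cache$out,
                        cache$inv, gamma, cache$train)
  list(dX = res$dX, dgamma = as.numeric(res$dgamma),
       dbeta = as.numeric(res$dbeta))
}

bn_backward <- function(dY, gamma, cache) {
  if (cache$train) {
    res <- bn_bwd_cpp(dY, cache$xhat, cache$inv, gamma, TRUE)
  } else {
    res <- bn_bwd_cpp(dY, array(0, dim(dY)), cache$inv, gamma, FALSE)
  }
  list(dX = res$dX, dgamma = as.numeric(res$dgamma),
       dbeta = as.numeric(res$dbeta))
}

relu_forward <- function(X) {
  if (is.array(X) && length(dim(X)) == 3L) {
    out <- relu_fwd_cpp(X)
  } else {
    out <- X * (X > 0)
  }
  list(out = out, cache = out)
}

relu_backward <- function(dY, out) {
  if (is.array(dY) && length(dim(dY)) == 3L) {
    relu_bwd_cpp(dY, out)
  } else {
    dY * (out > 0)
  }
}

dense_forward <- function(X, W, b) {
  # X: (in, B); W: (out, in)
  list(out = W %*% X + b, cache = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = crossprod(W, dY), dW = dY %*% t(cache), db = rowSums(dY))
}

#' Softmax over the class dimension
#' @param logits matrix (classes x batch).
#' @return column-stochastic matrix.
#' @keywords internal
softmax_cols <- function(logits) {
  z <- logits - matrix(apply(logits, 2L, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(e), ncol(e), byrow = TRUE)
}

log_softmax_cols <- function(logits) {
  mx <- apply(logits, 2L, max)
  z <- logits - matrix(mx, nrow(logits), ncol(logits), byrow = TRUE)
  lse <- log(colSums(exp(z)))
  z - matrix(lse, nrow(z), ncol(z), byrow = TRUE)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("_W$", nm)) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' @useDynLib indelrate, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
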