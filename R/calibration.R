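# Turning raw softmax outputs into calibrated per-junction, per-class
# mutation rates: Dirichlet calibration on held-out data, the Poisson
# recurrence correction, genome-rate scaling and spectrum-matched scaling
# for cross-model aggregation. The pipeline order is fixed:
# Dirichlet -> Poisson -> scaling.

DIRICHLET_EPS <- 1e-10
ODIR_LAMBDA <- 1e-4

#' Fit Dirichlet calibration parameters
#'
#' Learns the map `softmax(W %*% log(p + eps) + b)` minimizing multinomial
#' negative log-likelihood on a validation set, with a light L2 penalty on
#' the off-diagonal of W (ODIR-style) for identifiability.
#'
#' @param probs N x (n+1) matrix of raw predicted probabilities (rows on
#'   the simplex).
#' @param labels integer labels in `[0, n]`.
#' @param max_iter optimizer iteration cap.
#' @return a `dirichlet_params` list with `W`, `b`, `eps`.
#' @export
fit_dirichlet <- function(probs, labels, max_iter = 200L) {
  C <- ncol(probs)
  if (!all(0:(C - 1L) %in% labels)) {
    stop("every class must appear at least once in the validation labels")
  }
  N <- nrow(probs)
  LP <- t(log(probs + DIRICHLET_EPS))          # C x N
  Y <- matrix(0, C, N)
  Y[cbind(labels + 1L, seq_len(N))] <- 1
  offdiag <- 1 - diag(C)
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(C * C)], C, C),
         b = theta[C * C + seq_len(C)])
  }
  fn <- function(theta) {
    pp <- unpack(theta)
    Z <- pp$W %*% LP + pp$b
    nll <- -sum(Y * log_softmax_cols(Z)) / N
    nll + ODIR_LAMBDA * sum((pp$W * offdiag)^2)
  }
  gr <- function(theta) {
    pp <- unpack(theta)
    Z <- pp$W %*% LP + pp$b
    D <- (softmax_cols(Z) - Y) / N              # C x N
    dW <- D %*% t(LP) + 2 * ODIR_LAMBDA * (pp$W * offdiag)
    db <- rowSums(D)
    c(as.vector(dW), db)
  }
  theta0 <- c(as.vector(diag(C)), numeric(C))
  res <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  pp <- unpack(res$par)
  structure(list(W = pp$W, b = pp$b, eps = DIRICHLET_EPS,
                 nll = res$value), class = "dirichlet_params")
}

#' Apply Dirichlet calibration
#' @param params a `dirichlet_params`.
#' @param probs N x (n+1) matrix (or a single probability vector).
#' @return calibrated matrix of the same shape (rows on the simplex).
#' @export
apply_dirichlet <- function(params, probs) {
  vec <- is.null(dim(probs))
  if (vec) probs <- matrix(probs, nrow = 1L)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("input rows must lie on the probability simplex")
  }
  Z <- params$W %*% t(log(probs + params$eps)) + params$b
  out <- t(softmax_cols(Z))
  if (vec) out[1L, ] else out
}

#' Top-label expected calibration error and reliability curve
#'
#' Equal-width confidence bins on the top-label probability:
#' `ECE = sum_b |B_b|/N * |acc(B_b) - conf(B_b)|`.
#'
#' @param probs N x (n+1) probability matrix.
#' @param labels integer labels in `[0, n]`.
#' @param bins number of bins (>= 2).
#' @return list with `ece` and `curve` (data.frame bin, n, confidence,
#'   accuracy).
#' @export
ece <- function(probs, labels, bins = 10L) {
  stopifnot(bins >= 2L)
  if (nrow(probs) == 0L) stop("empty input")
  conf <- apply(probs, 1L, max)
  pred <- max.col(probs, ties.method = "first") - 1L
  correct <- pred == labels
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(pmax(findInterval(conf, edges, rightmost.closed = TRUE), 1L),
              bins)
  N <- length(conf)
  rows <- lapply(seq_len(bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               confidence = if (any(sel)) mean(conf[sel]) else NA_real_,
               accuracy = if (any(sel)) mean(correct[sel]) else NA_real_)
  })
  curve <- do.call(rbind, rows)
  filled <- curve[curve$n > 0, ]
  val <- sum(filled$n / N * abs(filled$accuracy - filled$confidence))
  list(ece = val, curve = curve)
}

#' @rdname ece
#' @export
reliability_curve <- function(probs, labels, bins = 10L) {
  ece(probs, labels, bins)$curve
}

#' Poisson recurrence correction
#'
#' Converts per-class mutation probabilities into event rates accounting
#' for possible recurrent mutation: `lambda = -ln(1 - sum(p))` and
#' `p_calib_i = lambda * p_i / sum(p)`.
#'
#' @param p numeric vector (classes 1..n) or N x n matrix of per-class
#'   mutation probabilities (class 0 excluded).
#' @return for a vector: list with `lambda` and `p_calib`; for a matrix:
#'   list with vectors `lambda` and matrix `p_calib`.
#' @export
poisson_correct <- function(p) {
  if (is.null(dim(p))) {
    if (any(p < 0)) stop("negative probability")
    s <- sum(p)
    if (s >= 1) stop("sum of mutation probabilities must be < 1")
    if (s == 0) return(list(lambda = 0, p_calib = p * 0))
    lambda <- -log1p(-s)
    list(lambda = lambda, p_calib = lambda * p / s)
  } else {
    if (any(p < 0)) stop("negative probability")
    s <- rowSums(p)
    if (any(s >= 1)) stop("sum of mutation probabilities must be < 1")
    lambda <- ifelse(s > 0, -log1p(-s), 0)
    fac <- ifelse(s > 0, lambda / s, 0)
    list(lambda = lambda, p_calib = p * fac)
  }
}

#' Scale rates so the expected count over a site set matches a genome rate
#'
#' `f_mut = mu_genome * |S| / sum_{i in S} p_i`; scaled rates are
#' `p * f_mut`, so the mean scaled rate over S equals `mu_genome` exactly.
#'
#' @param p numeric vector of per-site rates over the scaling set S.
#' @param mu_genome per-bp per-generation genome-wide rate (human de novo
#'   INDEL value: 1.5e-9).
#' @return list with `scaled`, `f_mut`, `mu_genome`, `n_sites`,
#'   `expected_count`.
#' @export
scale_rates <- function(p, mu_genome = 1.5e-9) {
  stopifnot(mu_genome > 0)
  tot <- sum(p)
  if (tot <= 0) stop("all-zero rate track")
  f_mut <- mu_genome * length(p) / tot
  list(scaled = p * f_mut, f_mut = f_mut, mu_genome = mu_genome,
       n_sites = length(p), expected_count = mu_genome * length(p))
}

#' Spectrum-matched per-class scaling
#'
#' Scales each length class c by `f_c = mu_c * |S| / sum_i p_{i,c}` so the
#' expected class-c count over S matches the target spectrum (e.g. a
#' de novo INDEL spectrum) prior to aggregation across models.
#'
#' @param p_classes N x n matrix of per-site, per-class rates.
#' @param mu_classes length-n vector of per-class target rates.
#' @return list with `scaled` (N x n), `f_c` (length n).
#' @export
scale_to_spectrum <- function(p_classes, mu_classes) {
  stopifnot(ncol(p_classes) == length(mu_classes))
  sums <- colSums(p_classes)
  if (any(sums <= 0)) stop("zero-mass class in scaling set")
  f_c <- mu_classes * nrow(p_classes) / sums
  list(scaled = sweep(p_classes, 2L, f_c, `*`), f_c = f_c)
}

#' Full calibration pipeline for a prediction track
#'
#' Dirichlet calibration of the (n+1)-class vectors, Poisson correction of
#' the mutation classes, then genome-rate scaling of the summed rate.
#'
#' @param track data.frame from [predict_genome()] (contig, junction,
#'   p0..pn).
#' @param dirichlet a `dirichlet_params` (or NULL to skip).
#' @param mu_genome genome-wide rate for scaling (or NULL to skip).
#' @return the track with per-class calibrated rate columns `r1..rn` and
#'   `rate` (summed, scaled when `mu_genome` given); attribute `f_mut`.
#' @export
calibrate_track <- function(track, dirichlet = NULL, mu_genome = NULL) {
  pcols <- grep("^p[0-9]+$", names(track), value = TRUE)
  P <- as.matrix(track[, pcols])
  if (!is.null(dirichlet)) P <- apply_dirichlet(dirichlet, P)
  pc <- poisson_correct(P[, -1L, drop = FALSE])
  R <- pc$p_calib
  f_mut <- NA_real_
  if (!is.null(mu_genome)) {
    sc <- scale_rates(rowSums(R), mu_genome)
    R <- R * sc$f_mut
    f_mut <- sc$f_mut
  }
  out <- track[, c("contig", "junction")]
  colnames(R) <- paste0("r", seq_len(ncol(R)))
  out <- cbind(out, as.data.frame(R))
  out$rate <- rowSums(R)
  attr(out, "f_mut") <- f_mut
  out
}
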