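test_that("Dirichlet map with identity parameters is the identity", {
  C <- 4L
  params <- structure(list(W = diag(C), b = numeric(C), eps = 1e-10),
                      class = "dirichlet_params")
  set.seed(1)
  P <- random_simplex(200, C)
  P <- pmax(P, 1e-3)
  P <- P / rowSums(P)
  out <- apply_dirichlet(params, P)
  expect_equal(out, P, tolerance = 1e-6)
})

test_that("Dirichlet map is permutation-equivariant and matches hand math", {
  C <- 3L
  perm <- matrix(0, C, C)
  perm[cbind(1:3, c(2, 3, 1))] <- 1
  params <- structure(list(W = perm, b = numeric(C), eps = 0),
                      class = "dirichlet_params")
  p <- c(0.5, 0.3, 0.2)
  # z = perm %*% log(p); softmax(z) by hand
  z <- as.vector(perm %*% log(p))
  hand <- exp(z) / sum(exp(z))
  expect_equal(as.numeric(apply_dirichlet(params, p)), hand)
  expect_error(apply_dirichlet(params, c(0.9, 0.9, 0.9)), "simplex")
})

test_that("fitting on well-calibrated inputs does not hurt the NLL", {
  set.seed(2)
  N <- 1500L
  C <- 3L
  P <- random_simplex(N, C)
  labels <- vapply(seq_len(N), function(i) sample(0:(C - 1), 1, prob = P[i, ]),
                   0L)
  nll <- function(Q) -mean(log(Q[cbind(seq_len(N), labels + 1L)]))
  params <- fit_dirichlet(P, labels)
  expect_lte(nll(apply_dirichlet(params, P)), nll(P) + 1e-6)
  # outputs stay on the simplex
  out <- apply_dirichlet(params, random_simplex(10000, C))
  expect_true(all(out >= 0))
  expect_equal(rowSums(out), rep(1, 10000), tolerance = 1e-9)
})

test_that("fitting corrects a temperature distortion", {
  set.seed(3)
  N <- 1500L
  C <- 3L
  Ptrue <- random_simplex(N, C)
  labels <- vapply(seq_len(N), function(i) sample(0:2, 1, prob = Ptrue[i, ]), 0L)
  Pdist <- Ptrue^2
  Pdist <- Pdist / rowSums(Pdist)
  nll <- function(Q) -mean(log(pmax(Q[cbind(seq_len(N), labels + 1L)], 1e-12)))
  params <- fit_dirichlet(Pdist, labels)
  expect_lt(nll(apply_dirichlet(params, Pdist)), nll(Pdist))
  expect_error(fit_dirichlet(Pdist[labels != 2, ], labels[labels != 2]),
               "every class")
})

test_that("top-label ECE handles the degenerate and hand cases", {
  # always confident and right -> 0
  P <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(ece(P, c(0L, 0L))$ece, 0)
  # always confident and wrong -> 1
  expect_equal(ece(P, c(1L, 1L))$ece, 1)
  # hand 4-example case, bins 10: confidences .95/.95/.55/.55
  P2 <- rbind(c(0.95, 0.05), c(0.95, 0.05), c(0.55, 0.45), c(0.45, 0.55))
  labels <- c(0L, 1L, 0L, 0L)
  # bin 10: conf .95, acc .5 -> |.45|*2/4 ; bin 6: conf .55, acc (1,0)
  hand <- 2 / 4 * abs(0.5 - 0.95) + 2 / 4 * abs(0.5 - 0.55)
  expect_equal(ece(P2, labels)$ece, hand)
  curve <- reliability_curve(P2, labels)
  expect_equal(nrow(curve), 10L)
  expect_equal(sum(curve$n), 4L)
})

test_that("Poisson correction matches its closed form", {
  # zero mutation probability is a fixed point
  z <- poisson_correct(rep(0, 7))
  expect_equal(z$lambda, 0)
  expect_equal(z$p_calib, rep(0, 7))
  # single class: lambda = -ln(0.9), all mass on that class
  one <- poisson_correct(c(0.1, 0, 0))
  expect_equal(one$lambda, -log(0.9), tolerance = 1e-15)
  expect_equal(one$p_calib, c(-log(0.9), 0, 0))
  # correction factor tends to 1 from above as total probability -> 0
  tinyp <- poisson_correct(c(5e-7, 5e-7))
  ratio <- tinyp$lambda / 1e-6
  expect_gte(ratio, 1)
  expect_lte(ratio, 1 + 1e-5)
  expect_error(poisson_correct(c(0.7, 0.4)), "< 1")
})

test_that("Poisson correction is monotone and never shrinks probabilities", {
  set.seed(4)
  for (i in 1:50) {
    p <- stats::runif(6, 0, 0.15)
    out <- poisson_correct(p)
    expect_true(all(out$p_calib >= p))
    expect_gte(out$lambda, sum(p))
    expect_equal(sum(out$p_calib), out$lambda)
    # raising one component raises its calibrated value
    p2 <- p
    p2[3] <- p2[3] + 0.01
    expect_gt(poisson_correct(p2)$p_calib[3], out$p_calib[3])
  }
  # matrix form agrees with rowwise application
  P <- matrix(stats::runif(20, 0, 0.1), 5, 4)
  M <- poisson_correct(P)
  for (i in 1:5) {
    expect_equal(M$p_calib[i, ], poisson_correct(P[i, ])$p_calib)
  }
})

test_that("genome-rate scaling is exact", {
  # worked example: 1000 sites at p = 1e-3, human mu = 1.5e-9
  p <- rep(1e-3, 1000)
  sc <- scale_rates(p, mu_genome = 1.5e-9)
  expect_equal(sc$f_mut, 1.5e-6)
  expect_equal(sc$scaled, rep(1.5e-9, 1000))
  expect_equal(mean(sc$scaled), 1.5e-9, tolerance = 1e-12)
  # doubling p halves f_mut, scaled rates unchanged
  sc2 <- scale_rates(2 * p, mu_genome = 1.5e-9)
  expect_equal(sc2$f_mut, sc$f_mut / 2)
  expect_equal(sc2$scaled, sc$scaled)
  # hand 3-site track
  sc3 <- scale_rates(c(0.1, 0.2, 0.7), mu_genome = 2e-9)
  expect_equal(sc3$f_mut, 2e-9 * 3 / 1)
  # exactness on random tracks
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(500)
    sc <- scale_rates(p, 1.5e-9)
    expect_lt(abs(mean(sc$scaled) - 1.5e-9) / 1.5e-9, 1e-12)
  }
  expect_error(scale_rates(rep(0, 5), 1.5e-9), "zero")
})

test_that("spectrum-matched scaling hits per-class targets exactly", {
  set.seed(6)
  P <- matrix(stats::runif(300, 0, 0.01), 100, 3)
  mu <- c(3e-9, 1e-9, 0.5e-9)
  out <- scale_to_spectrum(P, mu)
  expect_equal(colSums(out$scaled), mu * 100, tolerance = 1e-12)
  # two classes with target ratio 3:1 scale to sums in ratio 3:1
  out2 <- scale_to_spectrum(P[, 1:2], c(3e-9, 1e-9))
  expect_equal(sum(out2$scaled[, 1]) / sum(out2$scaled[, 2]), 3)
  # single class reduces to scale_rates
  out1 <- scale_to_spectrum(P[, 1, drop = FALSE], 1.5e-9)
  expect_equal(as.numeric(out1$scaled), scale_rates(P[, 1], 1.5e-9)$scaled)
  expect_error(scale_to_spectrum(cbind(P[, 1], 0), c(1e-9, 1e-9)),
               "zero-mass")
})

test_that("full track calibration applies Dirichlet, Poisson and scaling in order", {
  set.seed(7)
  track <- data.frame(contig = "c1", junction = 1:50)
  P <- random_simplex(50, 3)
  track$p0 <- P[, 1]; track$p1 <- P[, 2]; track$p2 <- P[, 3]
  out <- calibrate_track(track, dirichlet = NULL, mu_genome = 1.5e-9)
  expect_equal(mean(out$rate), 1.5e-9, tolerance = 1e-12)
  # without scaling, the per-junction rate is the Poisson-corrected sum
  out2 <- calibrate_track(track, dirichlet = NULL, mu_genome = NULL)
  expect_equal(out2$rate, -log(1 - (P[, 2] + P[, 3])), tolerance = 1e-12)
})
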