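test_that("gradient x input is zero at padding and matches finite differences", {
  tm <- toy_model()
  model <- tm$model
  fx <- tm$fixture
  ctg <- names(fx$genome)[1L]
  # junction 1: most of the upstream flank is padding
  w <- fetch_window(fx$genome, ctg, 1L, model$cfg$L)
  A <- grad_x_input(model, w, target_class = 1L)
  pad_cols <- which(colSums(w) == 0)
  expect_true(length(pad_cols) > 0)
  expect_true(all(A[, pad_cols] == 0))
  # finite-difference check of the input gradient at random positions
  g <- indelrate:::input_gradient(model, w, 1L)$dX[, , 1]
  f <- function(W) unet_forward(model, W)$logits[2, 1]
  set.seed(1)
  eps <- 1e-4
  for (t in 1:10) {
    i <- sample(4, 1); l <- sample(model$cfg$L, 1)
    wp <- w; wp[i, l] <- wp[i, l] + eps
    wm <- w; wm[i, l] <- wm[i, l] - eps
    num <- (f(wp) - f(wm)) / (2 * eps)
    expect_equal(g[i, l], num, tolerance = 1e-3)
  }
})

test_that("integrated gradients vanish on the zero path and converge to
           the completeness identity", {
  tm <- toy_model()
  model <- tm$model
  fx <- tm$fixture
  ctg <- names(fx$genome)[1L]
  w <- fetch_window(fx$genome, ctg, 5000L, model$cfg$L)
  # input == baseline -> all-zero attribution
  A0 <- integrated_gradients(model, w, 1L, steps = 16L, baseline = w)
  expect_equal(max(abs(A0)), 0)
  # the Riemann sum approaches F(x) - F(baseline) as steps grow; the path
  # derivative of a small batch-normalized network oscillates, so the
  # identity holds in the limit rather than at coarse step counts
  Fx <- unet_forward(model, w)$logits[2, 1]
  F0 <- unet_forward(model, matrix(0, 4, model$cfg$L))$logits[2, 1]
  dF <- Fx - F0
  errs <- vapply(c(32L, 2048L), function(st) {
    A <- integrated_gradients(model, w, 1L, steps = st, batch_steps = 256L)
    abs(sum(A) - dF)
  }, 0)
  expect_lt(errs[2], 0.05 * abs(dF))
  expect_lt(errs[2], errs[1] + 1e-8)
})

test_that("seqlet extraction finds rectangular bumps", {
  L <- 256L
  A <- matrix(0, 4, L)
  expect_equal(nrow(extract_seqlets(A, smooth = 0L)), 0L)
  # one bump of width 8 centred in the window
  A[1, 125:132] <- 1
  s1 <- extract_seqlets(A, threshold_quantile = 0.5, min_len = 4L,
                        smooth = 0L)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$offset_start, 125L)
  expect_equal(s1$offset_end, 132L)
  # two bumps separated by more than the merge gap stay separate
  A2 <- matrix(0, 4, L)
  A2[1, 110:115] <- 1
  A2[1, 140:145] <- 1
  s2 <- extract_seqlets(A2, threshold_quantile = 0.25, min_len = 4L,
                        merge_gap = 2L, smooth = 0L)
  expect_equal(nrow(s2), 2L)
  # and merge when the gap is small enough
  s3 <- extract_seqlets(A2, threshold_quantile = 0.25, min_len = 4L,
                        merge_gap = 30L, smooth = 0L)
  expect_equal(nrow(s3), 1L)
})

test_that("PWM, IC and CWM match hand computation; trimming removes
           low-IC flanks", {
  oh <- function(s) {
    m <- matrix(0, 4, nchar(s), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(nchar(s))) m[substr(s, i, i), i] <- 1
    m
  }
  seqs <- c("ACGT", "ACGA", "ACGC", "ACGG")
  seqlets <- lapply(seqs, function(s) {
    list(onehot = oh(s), attr = oh(s) * 2, score = 1)
  })
  m <- build_motif(seqlets)
  expect_equal(m$PWM[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(m$PWM[, 4]), rep(0.25, 4))
  # IC: 2 bits for a fixed column, 0 for uniform
  expect_equal(m$ic[1], 2)
  expect_equal(m$ic[4], 0)
  # CWM = mean over seqlets of onehot * attribution
  expect_equal(unname(m$CWM[1, 1]), 2)
  expect_equal(sum(m$CWM[, 4]), 2)
  expect_equal(m$contribution, sum(m$CWM))
  trimmed <- trim_motif(m)
  expect_equal(ncol(trimmed$PWM), 3L)
  expect_equal(trimmed$consensus, "ACG")
  # trimming away everything is an error
  uniform <- build_motif(lapply(c("ACGT", "CGTA", "GTAC", "TACG"),
                                function(s) list(onehot = oh(s),
                                                 attr = oh(s), score = 1)))
  expect_error(trim_motif(uniform), "width-0")
})

test_that("simple-repeat annotation finds homopolymer and dinucleotide runs", {
  g <- genome_from_strings(c(c1 = "ACGTAAAAAACGTGTGTGTACGT"))
  # positions: AAAAAA at 5-10; GTGTGTGT at 12-19 (4 GT units incl. G at 12)
  reps <- simple_repeats(g, mono_min = 6L, di_min = 3L, flank = 0L)
  mono <- reps[reps$type == "mono", ]
  expect_equal(mono$start, 4L)   # 0-based
  expect_equal(mono$end, 10L)
  di <- reps[reps$type == "di", ]
  expect_equal(nrow(di), 1L)
  expect_gte(di$start + 1L, 11L)
  expect_gte(di$end - di$start, 6L)
  # flanks widen the exclusion zone
  reps5 <- simple_repeats(g, mono_min = 6L, di_min = 3L, flank = 5L)
  expect_equal(reps5$start[reps5$type == "mono"], max(0L, 4L - 5L))
  # homopolymers are not reported as dinucleotide repeats
  g2 <- genome_from_strings(c(c1 = "CCCCCCCC"))
  reps2 <- simple_repeats(g2, mono_min = 6L, di_min = 3L, flank = 0L)
  expect_true(all(reps2$type == "mono"))
})

test_that("motif filters apply the three criteria conjunctively", {
  fx <- tiny_fixture()
  g <- fx$genome
  ctg <- names(g)[1L]
  tm <- toy_model()
  oh <- function(s) {
    m <- matrix(0, 4, nchar(s), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(nchar(s))) m[substr(s, i, i), i] <- 1
    m
  }
  mk_motif <- function(s, contrib) {
    sq <- list(onehot = oh(s), attr = oh(s) * contrib, score = contrib)
    build_motif(list(sq, sq, sq))
  }
  # CTTACG occurs often (planted); a long specific motif will be rare.
  # four candidates so the median contribution sits strictly below the
  # strongest CTTACG motif
  motifs <- list(mk_motif("CTTACG", 5), mk_motif("ACGTACGTACGT", 10),
                 mk_motif("CTTACG", 0.1), mk_motif("CTTACG", 0.2))
  occ <- kmer_occurrences(g, "CTTACG")
  # hyper set: motif-containing sites plus motif-free background sites
  # with no nearby observed variants, so criterion (i) has contrast
  elig <- eligible_junctions(fx$mask, ctg)
  occ_j <- occ$start1 + 2L
  far <- elig[!(elig %in% unlist(lapply(occ$start1, function(s)
    (s - 110L):(s + 110L))))]
  set.seed(3)
  hyper <- data.frame(contig = ctg,
                      junction = c(occ_j[1:80], sample(far, 80)))
  # observed variants concentrated at motif junctions
  observed <- do.call(rbind, lapply(occ$start1, function(s)
    data.frame(contig = ctg, junction = s:(s + 4L))))
  out <- filter_motifs(motifs, tm$model, g, hyper, observed)
  rep <- out$report
  # the rare 12-mer fails the occurrence criterion (strict > 100)
  expect_false(rep$occurrence_pass[2])
  # the low-contribution CTTACG motifs fail the median criterion (strict >)
  expect_false(rep$contribution_pass[3])
  expect_true(rep$retained[1])
  expect_equal(length(out$retained), 1L)
})

test_that("MEME export writes column-stochastic matrices", {
  oh <- function(s) {
    m <- matrix(0, 4, nchar(s), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(nchar(s))) m[substr(s, i, i), i] <- 1
    m
  }
  m <- build_motif(list(list(onehot = oh("CTTACG"), attr = oh("CTTACG"),
                             score = 1)))
  path <- tempfile(fileext = ".meme")
  write_meme(list(m), path)
  lines <- readLines(path)
  expect_true(any(grepl("MOTIF CTTACG", lines)))
  expect_true(any(grepl("alength= 4 w= 6", lines)))
})
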