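test_that("DR scores follow the rank formula and its exact distribution", {
  # 10 windows, strictly increasing stat
  set.seed(1)
  track <- data.frame(contig = "c1", junction = 0:999,
                      rate = rep(1, 1000))
  # observed counts per window arranged to be increasing with position
  observed <- data.frame(contig = "c1",
                         junction = unlist(lapply(1:9, function(w)
                           seq(w * 100, w * 100 + w * 3 - 1))))
  neutral <- data.frame(contig = "c1", start = 0L, end = 1000L)
  dr <- dr_scores(observed, track, neutral, window = 100L, step = 100L)
  n <- nrow(dr)
  expect_equal(sort(dr$DR), 100 * (seq_len(n) - 0.5) / n)
  expect_equal(mean(dr$DR), 50)
  expect_equal(min(dr$DR), 50 / n)
  expect_equal(max(dr$DR), 100 - 50 / n)
  # the window with the lowest stat carries the lowest score
  expect_equal(dr$DR[which.min(dr$stat)], 100 * 0.5 / n)
})

test_that("DR correction factor calibrates E to the neutral set", {
  track <- data.frame(contig = "c1", junction = 0:999, rate = 0.01)
  observed <- data.frame(contig = "c1", junction = seq(0, 999, by = 100))
  neutral <- data.frame(contig = "c1", start = 0L, end = 1000L)
  dr <- dr_scores(observed, track, neutral, window = 500L, step = 250L)
  # neutral set: 10 observed / (1000 * 0.01) = 1 -> correction factor 1
  expect_equal(dr$E, c(5, 5), tolerance = 1e-12)  # 500 junctions * .01 * 1
  # O == E everywhere -> all stats 0, mean DR still 50
  expect_equal(dr$stat, c(0, 0))
  expect_equal(mean(dr$DR), 50)
  expect_error(dr_scores(observed, track, neutral[0, ], 500L, 250L), "empty")
})

test_that("k-mer density counts internal junctions only", {
  g <- genome_from_strings(c(c1 = "AACTTACGGGCTTACGTT"))
  # CTTACG occurs at 1-based starts 3 and 11; internal junctions are
  # start..start+4
  occ <- kmer_occurrences(g, "CTTACG")
  expect_equal(occ$start1, c(3L, 11L))
  observed <- data.frame(contig = "c1", junction = c(3L, 5L, 12L, 2L, 8L))
  # junctions 3,5 inside first occurrence (3..7); 12 inside second (12..16);
  # 2 and 8 are outside
  kd <- kmer_density(g, observed, "CTTACG")
  expect_equal(kd$count, 2L)
  expect_equal(kd$mutations, 3L)
  expect_equal(kd$density, 3 / (2 * 5))
  # absent motif is flagged rather than divided by zero
  expect_true(is.na(kmer_density(g, observed, "GGGGGG")$density))
  # no observed mutations -> density 0
  kd0 <- kmer_density(g, observed[0, ], "CTTACG")
  expect_equal(kd0$density, 0)
})

test_that("all-kmer densities agree with per-kmer counting", {
  fx <- tiny_fixture()
  g <- fx$genome
  ctg <- names(g)[1L]
  set.seed(2)
  observed <- data.frame(contig = ctg,
                         junction = sample(10:(g[[ctg]]$length - 10), 400))
  all3 <- all_kmer_densities(g, observed, 3L)
  expect_equal(sum(all3$count), g[[ctg]]$length - 3L + 1L)
  for (km in c("AAA", "ACG", "TTT")) {
    row <- all3[all3$kmer == km, ]
    single <- kmer_density(g, observed, km)
    expect_equal(row$count, single$count)
    expect_equal(row$mutations, single$mutations)
  }
})

test_that("densities of a k-mer and its reverse complement agree on a
           strand-symmetrized cohort", {
  fx <- tiny_fixture()
  g <- fx$genome
  ctg <- names(g)[1L]
  # symmetric observed set: every motif internal junction mutates
  occ_f <- kmer_occurrences(g, "CTTACG")
  occ_r <- kmer_occurrences(g, "CGTAAG")
  mk_obs <- function(occ) {
    do.call(rbind, lapply(occ$start1, function(s)
      data.frame(contig = ctg, junction = s:(s + 4L))))
  }
  observed <- rbind(mk_obs(occ_f), mk_obs(occ_r))
  d1 <- kmer_density(g, observed, "CTTACG")
  d2 <- kmer_density(g, observed, "CGTAAG")
  expect_equal(d1$density, 1)
  expect_equal(d2$density, 1)
})

test_that("meta-gene profile reproduces flat and step tracks", {
  track <- data.frame(contig = "c1", junction = 0:19999, rate = 2)
  genes <- data.frame(contig = "c1", start = c(5000L, 12000L),
                      end = c(8000L, 15000L), strand = c("+", "-"))
  prof <- metagene_profile(track, genes, flank = 1000L,
                           body_scaled = 2000L, bin = 100L)
  expect_equal(nrow(prof), 40L)
  expect_equal(prof$region, rep(c("upstream", "body", "downstream"),
                                c(10, 20, 10)))
  expect_equal(prof$mean_rate, rep(2, 40))
  # step track: rate 0 inside bodies, 3 outside
  step <- track
  inside <- (step$junction >= 5000 & step$junction < 8000) |
    (step$junction >= 12000 & step$junction < 15000)
  step$rate <- ifelse(inside, 0, 3)
  prof2 <- metagene_profile(step, genes, 1000L, 2000L, 100L)
  expect_equal(prof2$mean_rate[prof2$region == "body"], rep(0, 20))
  expect_equal(prof2$mean_rate[prof2$region != "body"], rep(3, 20))
})

test_that("minus-strand genes are flipped to read 5' to 3'", {
  track <- data.frame(contig = "c1", junction = 0:9999,
                      rate = seq(0, 1, length.out = 10000))
  genes_fwd <- data.frame(contig = "c1", start = 4000L, end = 6000L,
                          strand = "+")
  genes_rev <- data.frame(contig = "c1", start = 4000L, end = 6000L,
                          strand = "-")
  pf <- metagene_profile(track, genes_fwd, 1000L, 2000L, 200L)
  pr <- metagene_profile(track, genes_rev, 1000L, 2000L, 200L)
  expect_equal(pr$mean_rate, rev(pf$mean_rate), tolerance = 1e-3)
})

test_that("strand-stratified densities are symmetric on symmetric data", {
  fx <- tiny_fixture()
  g <- fx$genome
  ctg <- names(g)[1L]
  genes <- data.frame(contig = ctg, start = 0L, end = g[[ctg]]$length,
                      strand = "+")
  occ_f <- kmer_occurrences(g, "CTTACG")
  occ_r <- kmer_occurrences(g, "CGTAAG")
  observed <- rbind(
    do.call(rbind, lapply(occ_f$start1, function(s)
      data.frame(contig = ctg, junction = s:(s + 4L)))),
    do.call(rbind, lapply(occ_r$start1, function(s)
      data.frame(contig = ctg, junction = s:(s + 4L)))))
  track <- data.frame(contig = ctg, junction = 0:g[[ctg]]$length,
                      rate = 1e-4)
  out <- strand_stratified_density(g, "CTTACG", genes, observed, track,
                                   n_bins = 4L)
  tr <- out$density[out$strand_category == "transcribed"]
  nt <- out$density[out$strand_category == "non_transcribed"]
  expect_equal(tr[!is.na(tr)], nt[!is.na(nt)], tolerance = 0.1)
  # strandless annotation is rejected
  genes2 <- genes
  genes2$strand <- "."
  expect_error(strand_stratified_density(g, "CTTACG", genes2, observed,
                                         track), "strandless")
})

test_that("thinned-observation regions fall to the bottom of the DR ranking", {
  # windows where observed events are thinned 5x against an intact rate
  # track should be strongly enriched in the lowest DR decile
  set.seed(3)
  len <- 200000L
  track <- data.frame(contig = "c1", junction = 0:(len - 1L), rate = 0.02)
  constrained <- rep(FALSE, len)
  starts <- seq(10000L, 190000L, by = 20000L)
  for (s in starts) constrained[(s + 1):(s + 2000)] <- TRUE
  p <- ifelse(constrained, 0.02 / 5, 0.02)
  hits <- which(stats::runif(len) < p) - 1L
  observed <- data.frame(contig = "c1", junction = hits)
  neutral <- data.frame(contig = "c1", start = 0L, end = 5000L)
  dr <- dr_scores(observed, track, neutral, window = 500L, step = 50L)
  mid <- (dr$start + dr$end) %/% 2L
  in_constrained <- constrained[mid + 1L]
  low <- dr$DR <= 10
  tab <- table(low, in_constrained)
  or <- (tab["TRUE", "TRUE"] / tab["TRUE", "FALSE"]) /
    (tab["FALSE", "TRUE"] / tab["FALSE", "FALSE"])
  expect_gt(or, 5)
})
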