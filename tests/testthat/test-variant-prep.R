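# Brute-force oracle: every candidate anchor whose edited haplotype equals
# the original edit's haplotype. Deliberately reconstructs full strings.
oracle_placements <- function(seq, v) {
  lr <- nchar(v$ref); la <- nchar(v$alt)
  apply_del <- function(s, p, d) paste0(substr(s, 1, p), substr(s, p + d + 1, nchar(s)))
  apply_ins <- function(s, p, ins) paste0(substr(s, 1, p), ins, substr(s, p + 1, nchar(s)))
  if (lr > la) {
    d <- lr - la
    target <- apply_del(seq, v$pos1, d)
    which(vapply(1:(nchar(seq) - d), function(q) {
      apply_del(seq, q, d) == target
    }, TRUE))
  } else {
    d <- la - lr
    ins <- substr(v$alt, 2, d + 1)
    target <- apply_ins(seq, v$pos1, ins)
    ok <- logical(nchar(seq))
    for (q in 1:nchar(seq)) {
      # any insertion of length d at q reproducing the target works
      cand <- substr(target, q + 1, q + d)
      ok[q] <- apply_ins(seq, q, cand) == target
    }
    which(ok)
  }
}

test_that("length classes: 1-6 individual, 7-20 pooled, >20 excluded", {
  b <- length_binning()
  expect_equal(b$n, 7L)
  expect_equal(length_class(1L, b), 1L)
  expect_equal(length_class(6L, b), 6L)
  expect_equal(length_class(7L, b), 7L)
  expect_equal(length_class(20L, b), 7L)
  expect_true(is.na(length_class(21L, b)))
  expect_error(length_class(0L, b))
})

test_that("hypergeometric downsampling obeys degenerate and analytic laws", {
  expect_equal(downsample_ac(200L, 200L, 100L, 1L), 100L)
  expect_equal(downsample_ac(200L, 0L, 100L, 1L), 0L)
  # mean of draws vs analytic expectation AN_down*AC/AN = 3.7
  set.seed(99)
  draws <- stats::rhyper(100000, m = 37, n = 2000 - 37, k = 200)
  mu <- 200 * 37 / 2000
  v <- 200 * (37 / 2000) * (1 - 37 / 2000) * (2000 - 200) / 1999
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 100000))
  # chi-square GOF against the analytic pmf
  kk <- 0:15
  pmf <- stats::dhyper(kk, 37, 2000 - 37, 200)
  obs <- tabulate(draws + 1L, nbins = 16)
  keep <- pmf * 100000 >= 5
  chi <- sum((obs[keep] - 100000 * pmf[keep])^2 / (100000 * pmf[keep]))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("rare extraction keeps singletons, one per position", {
  v <- data.frame(contig = "c1", pos1 = c(10L, 10L, 20L, 30L),
                  ref = c("A", "A", "C", "G"),
                  alt = c("AT", "AG", "CA", "GTT"),
                  AC = c(1L, 1L, 500L, 500L), AN = 500L,
                  stringsAsFactors = FALSE)
  out <- extract_rare(v, AN_down = 500L, rng_seed = 1L)
  # fixed variants downsample to AC_down = AN_down != 1 -> excluded;
  # the two singletons at pos 10 collapse to one
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos1, 10L)
  expect_equal(out$AC, 1L)
  expect_equal(out$AN, 500L)
  expect_error(extract_rare(v[, -5], 100L), "missing")
})

test_that("equivalent placements match hand examples", {
  g <- genome_from_strings(c(c1 = "CAAAT"))
  # delete one A: three equivalent anchors (C|A A A)
  del <- data.frame(contig = "c1", pos1 = 1L, ref = "CA", alt = "C",
                    stringsAsFactors = FALSE)
  pl <- enumerate_placements(g, del)
  expect_equal(pl$pos1, c(1L, 2L, 3L))
  # insert A into the A run: anchors 1..4 all give CAAAAT
  ins <- data.frame(contig = "c1", pos1 = 1L, ref = "C", alt = "CA",
                    stringsAsFactors = FALSE)
  pli <- enumerate_placements(g, ins)
  expect_equal(pli$pos1, 1:4)
  # non-repeat deletion has exactly one placement
  g2 <- genome_from_strings(c(c1 = "ACGT"))
  del2 <- data.frame(contig = "c1", pos1 = 1L, ref = "AC", alt = "A",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_placements(g2, del2)), 1L)
})

test_that("placements equal the brute-force haplotype oracle on random contexts", {
  set.seed(11)
  for (trial in 1:250) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    g <- genome_from_strings(c(c1 = s))
    d <- sample(1:3, 1)
    p <- sample(5:(50 - d - 2), 1)
    if (runif(1) < 0.5) {
      v <- data.frame(contig = "c1", pos1 = p,
                      ref = substr(s, p, p + d), alt = substr(s, p, p),
                      stringsAsFactors = FALSE)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), d, replace = TRUE),
                   collapse = "")
      v <- data.frame(contig = "c1", pos1 = p, ref = substr(s, p, p),
                      alt = paste0(substr(s, p, p), ins),
                      stringsAsFactors = FALSE)
    }
    expect_equal(enumerate_placements(g, v)$pos1, oracle_placements(s, v),
                 info = paste(s, v$pos1, v$ref, v$alt))
  }
})

test_that("placement assignment is uniform and seed-deterministic", {
  g <- genome_from_strings(c(c1 = "CAAAT"))
  del <- data.frame(contig = "c1", pos1 = 1L, ref = "CA", alt = "C",
                    stringsAsFactors = FALSE)
  pl <- enumerate_placements(g, del)
  expect_identical(assign_placement(pl, 5L), assign_placement(pl, 5L))
  picks <- vapply(1:3000, function(i) assign_placement(pl, i)$pos1, 0L)
  freq <- tabulate(picks, 3) / 3000
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  expect_error(assign_placement(pl[0, ]), "empty")
})

test_that("breakpoint decomposition: one junction per insertion, two per deletion", {
  v <- data.frame(contig = "c1", pos1 = c(10L, 10L, 10L),
                  ref = c("A", "ACGT", "A"),
                  alt = c("ACG", "A", paste0("A", strrep("T", 21))),
                  stringsAsFactors = FALSE)
  bp <- decompose_breakpoints(v)
  # 21-bp insertion excluded; insertion of 2 -> one site; deletion of 3 -> two
  expect_equal(nrow(bp), 3L)
  ins <- bp[bp$kind == "insertion", ]
  expect_equal(ins$junction, 10L)
  expect_equal(ins$length_class, 2L)
  expect_equal(bp$junction[bp$kind == "deletion_start"], 10L)
  expect_equal(bp$junction[bp$kind == "deletion_end"], 13L)
  expect_equal(unique(bp$length_class[bp$kind != "insertion"]), 3L)
})

test_that("site filtering applies coverage and interval exclusion", {
  g <- genome_from_strings(c(c1 = strrep("A", 100)))
  cov <- data.frame(contig = "c1", start = 0L, end = 100L, value = 30)
  m <- build_coverage_mask(cov, g, 30.5, 0.5)
  sites <- data.frame(contig = "c1", junction = c(5L, 50L, 95L),
                      kind = "insertion", length_class = 1L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(filter_sites(sites, m, NULL)), 3L)
  exon <- data.frame(contig = "c1", start = 40L, end = 60L)
  kept <- filter_sites(sites, m, exon)
  expect_equal(kept$junction, c(5L, 95L))
  # failing coverage at one flank removes the site
  cov2 <- rbind(cov, data.frame(contig = "c1", start = 5L, end = 6L,
                                value = 200))
  expect_error(build_coverage_mask(rbind(cov, cov2[2, ]), g, 30.5, 0.5),
               "conflicting")
  cov3 <- data.frame(contig = "c1", start = c(0L, 5L, 6L),
                     end = c(5L, 6L, 100L), value = c(30, 200, 30))
  m3 <- build_coverage_mask(cov3, g, 30.5, 0.5)
  expect_equal(filter_sites(sites, m3, NULL)$junction, c(50L, 95L))
})

test_that("mutation spectra and total-variation distance behave", {
  g <- genome_from_strings(c(c1 = "AACGTACGTT"))
  v <- data.frame(contig = "c1", pos1 = c(2L, 4L, 6L),
                  ref = c("A", "G", "A"),
                  alt = c("AT", "GAC", "A,CC"), stringsAsFactors = FALSE)
  v$alt <- c("AT", "GAC", "ACC")  # 1-bp ins, 2-bp ins, 2-bp ins
  sp <- spectrum(v, g)
  expect_equal(sum(sp$length_hist), 1)
  expect_equal(sum(sp$context_hist), 1)
  expect_equal(sp$ins_del_ratio, 1)
  expect_equal(unname(sp$length_hist["1"]), 1 / 3)
  expect_equal(spectrum_distance(sp, sp), 0)
  # hand-computed TV distance on two 3-variant sets
  v2 <- data.frame(contig = "c1", pos1 = c(2L, 4L, 6L),
                   ref = c("AC", "GT", "AC"), alt = c("A", "G", "A"),
                   stringsAsFactors = FALSE)
  sp2 <- spectrum(v2, g)
  expect_equal(sp2$ins_del_ratio, 0)
  # length hists: v = (1/3 at 1, 2/3 at 2); v2 = (1 at 1): TV = 2/3
  # context hists both concentrate on the same three 2-mers: TV = 0
  tv_len <- 0.5 * sum(abs(sp$length_hist - sp2$length_hist))
  expect_equal(tv_len, 2 / 3)
  expect_equal(spectrum_distance(sp, sp2),
               mean(c(tv_len, 0.5 * sum(abs(sp$context_hist - sp2$context_hist)))))
})

test_that("VCF round trip preserves INDEL records", {
  fx <- tiny_fixture()
  v <- head(fx$cohort[, c("contig", "pos1", "ref", "alt", "AC", "AN")], 50)
  path <- tempfile(fileext = ".vcf")
  write_indel_vcf(v, path)
  back <- read_indel_vcf(path)
  expect_equal(nrow(back), 50L)
  expect_equal(back$pos1, v$pos1)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$AC, v$AC)
  expect_equal(back$AN, v$AN)
  expect_true(all(back$kind %in% c("insertion", "deletion")))
})
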