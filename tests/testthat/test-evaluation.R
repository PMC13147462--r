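# brute-force per-junction scan used as the independent oracle for the
# k-mer and regional records
oracle_kmer_records <- function(genome, observed, track, k, p_col) {
  obs_key <- paste(observed$contig, observed$junction)
  rows <- list()
  for (i in seq_len(nrow(track))) {
    ctg <- genome[[track$contig[i]]]
    j <- track$junction[i]
    a <- j - k / 2 + 1
    b <- j + k / 2
    if (a < 1 || b > ctg$length) next
    km <- substr(ctg$seq, a, b)
    if (grepl("N", km)) next
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = km, p = track[[p_col]][i],
      m = as.integer(paste(track$contig[i], j) %in% obs_key))
  }
  df <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(df, df$kmer), function(d) {
    data.frame(kmer = d$kmer[1], m = sum(d$m), N = nrow(d),
               K_obs = sum(d$m) / nrow(d), K_pred = mean(d$p))
  }))
  out[order(out$kmer), ]
}

eval_setup <- function() {
  cached("eval_setup", function() {
    fx <- tiny_fixture()
    g <- fx$genome
    ctg <- names(g)[1L]
    set.seed(9)
    j <- sort(sample(100:9900, 3000))
    track <- data.frame(contig = ctg, junction = j,
                        rate = stats::runif(3000, 0, 1e-3),
                        stringsAsFactors = FALSE)
    observed <- data.frame(contig = ctg,
                           junction = sample(j, 200),
                           stringsAsFactors = FALSE)
    list(fx = fx, g = g, track = track, observed = observed)
  })
}

test_that("k-mer records equal the brute-force per-junction oracle", {
  es <- eval_setup()
  res <- kmer_correlation(es$g, es$observed, es$track, k = 2L, p_col = "rate")
  orc <- oracle_kmer_records(es$g, es$observed, es$track, 2L, "rate")
  expect_equal(res$records$kmer, orc$kmer)
  expect_equal(res$records$m, orc$m)
  expect_equal(res$records$N, orc$N)
  expect_equal(res$records$K_obs, orc$K_obs)
  expect_equal(res$records$K_pred, orc$K_pred, tolerance = 1e-12)
  expect_equal(res$report$pearson_r,
               stats::cor(orc$K_obs, orc$K_pred))
  # conservation: total observed count is preserved across k-mer records
  expect_equal(sum(res$records$m), nrow(es$observed))
})

test_that("an oracle predictor yields k-mer correlation exactly 1", {
  es <- eval_setup()
  base <- kmer_correlation(es$g, es$observed, es$track, 2L, "rate")
  perfect <- es$track
  lk <- junction_kmers(es$g, es$track$contig[1], es$track$junction, 2L)
  rate_by_kmer <- setNames(base$records$K_obs, base$records$kmer)
  perfect$rate <- as.numeric(rate_by_kmer[lk])
  perfect <- perfect[!is.na(perfect$rate), ]
  res <- kmer_correlation(es$g, es$observed, perfect, 2L, "rate")
  expect_equal(res$report$pearson_r, 1, tolerance = 1e-12)
})

test_that("(k+2)-mer records aggregate exactly to k-mer records", {
  es <- eval_setup()
  r2 <- kmer_correlation(es$g, es$observed, es$track, 2L, "rate")$records
  r4 <- kmer_correlation(es$g, es$observed, es$track, 4L, "rate")$records
  r4$central <- substr(r4$kmer, 2, 3)
  agg <- do.call(rbind, lapply(split(r4, r4$central), function(d) {
    data.frame(kmer = d$central[1], m = sum(d$m), N = sum(d$N))
  }))
  # junctions within k/2 of the contig edge or near Ns can drop out of the
  # larger context; here the surveyed junctions are interior and N-free
  common <- intersect(agg$kmer, r2$kmer)
  expect_equal(agg[common, "m"], r2$m[match(common, r2$kmer)])
  expect_equal(agg[common, "N"], r2$N[match(common, r2$kmer)])
})

test_that("Pearson r is invariant to affine rescaling of predictions", {
  es <- eval_setup()
  r1 <- kmer_correlation(es$g, es$observed, es$track, 2L, "rate")
  scaled <- es$track
  scaled$rate <- scaled$rate * 1.5e-6
  r2 <- kmer_correlation(es$g, es$observed, scaled, 2L, "rate")
  expect_equal(r1$report$pearson_r, r2$report$pearson_r, tolerance = 1e-12)
})

test_that("regional records apply the N > 20% median filter", {
  # hand case: bins with N = 100, 90, 80, 10 -> median 85, threshold 17
  track <- data.frame(
    contig = "c1",
    junction = c(seq(0, 990, length.out = 100),
                 seq(1000, 1990, length.out = 90),
                 seq(2000, 2990, length.out = 80),
                 seq(3000, 3990, length.out = 10)),
    rate = 1e-3)
  track$junction <- as.integer(track$junction)
  observed <- data.frame(contig = "c1", junction = track$junction[c(1, 101)])
  res <- regional_correlation(observed, track, bin_size = 1000L,
                              p_col = "rate")
  expect_equal(res$records$N, c(100, 90, 80, 10))
  expect_equal(res$records$passes_filter, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$report$n_points, 3L)
  expect_equal(res$records$R_obs[1], 1 / 100)
})

test_that("regional records equal a brute-force scan on the tiny fixture", {
  es <- eval_setup()
  res <- regional_correlation(es$observed, es$track, bin_size = 500L,
                              p_col = "rate")
  # brute force
  obs_key <- paste(es$observed$contig, es$observed$junction)
  bins <- unique(es$track$junction %/% 500L)
  for (b in sort(bins)) {
    sel <- es$track$junction %/% 500L == b
    N <- sum(sel)
    m <- sum(paste(es$track$contig[sel], es$track$junction[sel]) %in% obs_key)
    row <- res$records[res$records$bin_start == b * 500L, ]
    expect_equal(row$N, N)
    expect_equal(row$m, m)
    expect_equal(row$R_pred, mean(es$track$rate[sel]), tolerance = 1e-12)
  }
  # predictions identical to observations give r = 1
  ident <- es$track
  ident$rate <- as.numeric(paste(ident$contig, ident$junction) %in% obs_key)
  res2 <- regional_correlation(es$observed, ident, 500L, "rate")
  expect_equal(res2$report$pearson_r, 1, tolerance = 1e-12)
})

test_that("coefficient-of-variation comparison matches hand values", {
  rec <- data.frame(contig = "c1", bin_start = c(0, 1000, 2000),
                    m = c(2, 4, 6), N = c(100, 100, 100),
                    R_obs = c(0.02, 0.04, 0.06),
                    R_pred = c(0.03, 0.04, 0.05),
                    passes_filter = TRUE)
  cvres <- cv_compare(rec)
  expect_equal(cvres$cv_obs, stats::sd(c(0.02, 0.04, 0.06)) / 0.04)
  expect_equal(cvres$cv_pred, stats::sd(c(0.03, 0.04, 0.05)) / 0.04)
  expect_equal(cvres$delta_cv, abs(cvres$cv_obs - cvres$cv_pred))
  # identical rates give delta 0; constant rates give CV 0
  rec$R_pred <- rec$R_obs
  expect_equal(cv_compare(rec)$delta_cv, 0)
  rec$R_obs <- rec$R_pred <- 0.05
  expect_equal(cv_compare(rec)$cv_obs, 0)
})
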