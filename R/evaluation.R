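# Headline accuracy metrics: k-mer correlation (observed m_i/N_i vs
# predicted mean p over the k-mer's sites) and regional correlation over
# non-overlapping bins with the N > 20% * N_median filter, plus the
# coefficient-of-variation comparison.

#' k-mer context of junctions
#'
#' The k-mer at junction j0 consists of the k/2 bases immediately upstream
#' and the k/2 bases immediately downstream (1-based bases
#' j0-k/2+1 ... j0+k/2). Junctions whose context contains N or leaves the
#' contig return NA.
#'
#' @param genome `genome` object.
#' @param contig contig name.
#' @param junctions integer junction vector.
#' @param k even context size.
#' @return character vector of k-mers (NA where undefined).
#' @export
junction_kmers <- function(genome, contig, junctions, k) {
  if (k %% 2L != 0L || k < 2L) stop("k must be even and >= 2")
  ctg <- genome[[contig]]
  half <- k %/% 2L
  pos <- outer(seq_len(k) - half, junctions, `+`)   # k x B
  bad <- pos < 1L | pos > ctg$length
  codes <- matrix(0L, k, length(junctions))
  codes[!bad] <- ctg$code[pos[!bad]]
  km <- apply(codes, 2L, function(cc) {
    if (any(cc == 0L)) NA_character_ else
      paste(c("N", BASES)[cc + 1L], collapse = "")
  })
  km
}

#' k-mer correlation between observed and predicted rates
#'
#' For each k-mer subtype i over the surveyed junctions: observed rate
#' `K_obs = m_i / N_i` (m_i observed mutated sites, N_i sites carrying the
#' k-mer) and predicted rate `K_pred = sum_j p_j / N_i`; Pearson r across
#' k-mers with `N_i > 0`, each subtype one datapoint. k-mers containing N
#' are excluded.
#'
#' @param genome `genome` object.
#' @param observed breakpoint data.frame (contig, junction) of the surveyed
#'   mutation class.
#' @param track prediction data.frame (contig, junction, and the
#'   probability column named by `p_col`).
#' @param k even context size.
#' @param p_col column of `track` holding the per-junction predicted
#'   probability for the class under evaluation.
#' @return list with `report` (pearson_r, n_points, k) and `records`
#'   (data.frame kmer, m, N, K_obs, K_pred).
#' @export
kmer_correlation <- function(genome, observed, track, k, p_col = "rate") {
  if (k %% 2L != 0L) stop("k must be even")
  obs_key <- paste(observed$contig, observed$junction)
  recs <- new.env(parent = emptyenv())
  for (ctg in unique(track$contig)) {
    sel <- track$contig == ctg
    j <- track$junction[sel]
    p <- track[[p_col]][sel]
    km <- junction_kmers(genome, ctg, j, k)
    is_obs <- paste(ctg, j) %in% obs_key
    ok <- !is.na(km)
    df <- data.frame(km = km[ok], p = p[ok], m = as.integer(is_obs[ok]))
    agg_n <- tapply(rep(1L, nrow(df)), df$km, sum)
    agg_p <- tapply(df$p, df$km, sum)
    agg_m <- tapply(df$m, df$km, sum)
    for (kk in names(agg_n)) {
      prev <- recs[[kk]]
      if (is.null(prev)) prev <- c(0, 0, 0)
      recs[[kk]] <- prev + c(agg_n[[kk]], agg_p[[kk]], agg_m[[kk]])
    }
  }
  kms <- sort(ls(recs))
  if (length(kms) < 3L) stop("fewer than 3 k-mers with data")
  tab <- do.call(rbind, lapply(kms, function(kk) {
    v <- recs[[kk]]
    data.frame(kmer = kk, m = v[3L], N = v[1L],
               K_obs = v[3L] / v[1L], K_pred = v[2L] / v[1L],
               stringsAsFactors = FALSE)
  }))
  r <- stats::cor(tab$K_obs, tab$K_pred)
  list(report = list(metric = "kmer", k = k, pearson_r = r,
                     n_points = nrow(tab)),
       records = tab)
}

#' Regional correlation over non-overlapping bins
#'
#' Bins are anchored at coordinate 0 of each contig. For bin i:
#' `R_obs = m_i / N_i`, `R_pred = sum p_j / N_i` over the N_i surveyed
#' junctions in the bin. `N_median` is computed per contig over all its
#' bins; bins failing `N > 0.2 * N_median` are excluded from the
#' correlation.
#'
#' @inheritParams kmer_correlation
#' @param bin_size bin width in bp (>= 1).
#' @return list with `report` and `records` (contig, bin_start, m, N,
#'   R_obs, R_pred, passes_filter).
#' @export
regional_correlation <- function(observed, track, bin_size, p_col = "rate") {
  stopifnot(bin_size >= 1L)
  obs_key <- paste(observed$contig, observed$junction)
  out <- list()
  for (ctg in unique(track$contig)) {
    sel <- track$contig == ctg
    j <- track$junction[sel]
    p <- track[[p_col]][sel]
    is_obs <- paste(ctg, j) %in% obs_key
    bin <- j %/% bin_size
    all_bins <- seq.int(0L, max(bin))
    N <- tabulate(bin + 1L, nbins = max(bin) + 1L)
    psum <- vapply(all_bins, function(b) sum(p[bin == b]), 0)
    m <- vapply(all_bins, function(b) sum(is_obs[bin == b]), 0)
    Nmed <- median(N)
    out[[ctg]] <- data.frame(
      contig = ctg, bin_start = all_bins * bin_size, m = m, N = N,
      R_obs = ifelse(N > 0, m / N, NA_real_),
      R_pred = ifelse(N > 0, psum / N, NA_real_),
      passes_filter = N > 0.2 * Nmed, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, out)
  rownames(recs) <- NULL
  pass <- recs[recs$passes_filter, , drop = FALSE]
  if (nrow(pass) < 3L) stop("fewer than 3 passing bins")
  r <- stats::cor(pass$R_obs, pass$R_pred)
  list(report = list(metric = "regional", bin_size = bin_size,
                     pearson_r = r, n_points = nrow(pass)),
       records = recs)
}

#' Coefficient-of-variation comparison across passing bins
#'
#' CV = sd/mean (sample sd) of observed and predicted regional rates over
#' filter-passing bins; a smaller |CV_obs - CV_pred| indicates better
#' dispersion agreement.
#'
#' @param records the `records` from [regional_correlation()].
#' @return list with `cv_obs`, `cv_pred`, `delta_cv`.
#' @export
cv_compare <- function(records) {
  pass <- records[records$passes_filter & records$N > 0, , drop = FALSE]
  if (nrow(pass) < 2L) stop("need at least 2 passing bins")
  if (mean(pass$R_obs) == 0 || mean(pass$R_pred) == 0) stop("zero mean rate")
  cv <- function(x) sd(x) / mean(x)
  co <- cv(pass$R_obs); cp <- cv(pass$R_pred)
  list(cv_obs = co, cv_pred = cp, delta_cv = abs(co - cp))
}
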