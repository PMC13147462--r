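# Downstream consumers of the rate map: depletion-rank (DR) constraint
# scores over sliding windows, k-mer rare-variant density, strand-stratified
# motif density, and meta-gene rate profiles.

#' Depletion-rank scores over sliding windows
#'
#' For each 500-bp window stepped by 50 bp: O = observed INDEL count,
#' E = (sum of scaled rates in the window) * correction factor, where the
#' correction factor is the observed count over the summed rate in a set of
#' presumably neutral sites. Windows are ranked ascending by
#' `(O - E) / sqrt(E)` (stable ties by contig, start); the i-th lowest gets
#' `DR = 100 * (i - 0.5) / n`. Windows with E = 0 are dropped with a
#' warning.
#'
#' @param observed data.frame of observed variants (contig, junction).
#' @param rate_track data.frame (contig, junction, rate) of scaled rates.
#' @param neutral data.frame of neutral intervals (contig, start, end;
#'   0-based half-open).
#' @param window,step window size and step (bp).
#' @return data.frame contig, start, end, O, E, stat, DR.
#' @export
dr_scores <- function(observed, rate_track, neutral, window = 500L,
                      step = 50L) {
  if (is.null(neutral) || nrow(neutral) == 0L) stop("empty neutral set")
  # correction factor from neutral sites
  neut_obs <- 0L
  neut_rate <- 0
  for (i in seq_len(nrow(neutral))) {
    ctg <- neutral$contig[i]
    a <- neutral$start[i]; b <- neutral$end[i]
    sel <- rate_track$contig == ctg & rate_track$junction >= a &
      rate_track$junction < b
    neut_rate <- neut_rate + sum(rate_track$rate[sel])
    selo <- observed$contig == ctg & observed$junction >= a &
      observed$junction < b
    neut_obs <- neut_obs + sum(selo)
  }
  if (neut_rate <= 0) stop("neutral set has zero summed rate")
  corr <- neut_obs / neut_rate
  rows <- list()
  for (ctg in unique(rate_track$contig)) {
    sel <- rate_track$contig == ctg
    j <- rate_track$junction[sel]
    r <- rate_track$rate[sel]
    jo <- observed$junction[observed$contig == ctg]
    maxpos <- max(j)
    starts <- seq.int(0L, max(0L, maxpos - window), by = step)
    # cumulative sums over junction coordinate for O(1) window queries
    ord <- order(j)
    js <- j[ord]; rs <- r[ord]
    cum_r <- c(0, cumsum(rs))
    jos <- sort(jo)
    wnd_sum <- function(sorted, cum, a, b) {
      lo <- findInterval(a - 1L, sorted) + 1L
      hi <- findInterval(b, sorted)
      if (hi < lo) 0 else cum[hi + 1L] - cum[lo]
    }
    cum_o <- seq_along(jos)
    O <- vapply(starts, function(a) {
      lo <- findInterval(a - 1L, jos) + 1L
      hi <- findInterval(a + window - 1L, jos)
      max(0L, hi - lo + 1L)
    }, 0)
    E <- vapply(starts, function(a) {
      wnd_sum(js, cum_r, a, a + window - 1L)
    }, 0) * corr
    rows[[ctg]] <- data.frame(contig = ctg, start = starts,
                              end = starts + window, O = O, E = E,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  drop <- df$E == 0
  if (any(drop)) {
    warning(sum(drop), " windows with zero expected count dropped")
    df <- df[!drop, , drop = FALSE]
  }
  df$stat <- (df$O - df$E) / sqrt(df$E)
  ord <- order(df$stat, df$contig, df$start)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  df$DR <- 100 * (seq_len(n) - 0.5) / n
  rownames(df) <- NULL
  df
}

#' Occurrences of a k-mer on the forward strand
#' @param genome `genome` object.
#' @param kmer motif string (ACGT alphabet).
#' @return data.frame contig, start1 (1-based start of the occurrence).
#' @export
kmer_occurrences <- function(genome, kmer) {
  if (grepl("N", kmer)) stop("k-mer must not contain N")
  out <- list()
  for (ctg in names(genome)) {
    m <- Biostrings::matchPattern(kmer, Biostrings::DNAString(genome[[ctg]]$seq))
    if (length(m)) {
      out[[ctg]] <- data.frame(contig = ctg,
                               start1 = BiocGenerics::start(m),
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), start1 = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Average rare-variant density of a k-mer
#'
#' Counts observed variants whose assigned junction lies strictly inside an
#' occurrence (k-1 internal junctions per occurrence) and divides by
#' `count * (k - 1)`.
#'
#' @param genome `genome` object.
#' @param observed data.frame (contig, junction).
#' @param kmer motif string.
#' @param occurrences optional pre-computed occurrence table.
#' @return list with `kmer`, `count`, `mutations`, `density` (NA when the
#'   motif is absent).
#' @export
kmer_density <- function(genome, observed, kmer, occurrences = NULL) {
  k <- nchar(kmer)
  if (k < 2L) stop("k must be >= 2")
  occ <- if (is.null(occurrences)) kmer_occurrences(genome, kmer) else occurrences
  if (nrow(occ) == 0L) {
    return(list(kmer = kmer, count = 0L, mutations = 0L, density = NA_real_))
  }
  mut <- 0L
  for (ctg in unique(occ$contig)) {
    jo <- sort(observed$junction[observed$contig == ctg])
    if (!length(jo)) next
    st <- occ$start1[occ$contig == ctg]
    # internal junctions of occurrence at s: s, s+1, ..., s+k-2
    for (s in st) {
      lo <- findInterval(s - 1L, jo) + 1L
      hi <- findInterval(s + k - 2L, jo)
      if (hi >= lo) mut <- mut + (hi - lo + 1L)
    }
  }
  list(kmer = kmer, count = nrow(occ), mutations = mut,
       density = mut / (nrow(occ) * (k - 1L)))
}

#' Densities of all k-mers of a given size
#' @param genome `genome` object.
#' @param observed data.frame (contig, junction).
#' @param k k-mer size.
#' @return data.frame kmer, count, mutations, density.
#' @export
all_kmer_densities <- function(genome, observed, k) {
  # single pass over the genome: classify every k-mer start, then tally
  tallies <- new.env(parent = emptyenv())
  for (ctg in names(genome)) {
    code <- genome[[ctg]]$code
    n <- length(code)
    if (n < k) next
    # rolling k-mer id; invalid when any N in window
    valid <- code > 0L
    obs <- rep(0L, n)
    jo <- observed$junction[observed$contig == ctg]
    jo <- jo[jo >= 1L & jo <= n]
    if (length(jo)) {
      tb <- table(jo)
      obs[as.integer(names(tb))] <- as.integer(tb)
    }
    cum_obs <- c(0L, cumsum(obs))
    starts <- seq_len(n - k + 1L)
    # internal-junction mutation count for window starting at s:
    # junctions s .. s+k-2  -> cum_obs[s+k-1] - cum_obs[s]
    muts <- cum_obs[starts + k - 1L] - cum_obs[starts]
    # vectorized validity via cumulative sum of invalid positions
    inv <- c(0L, cumsum(!valid))
    ok <- (inv[starts + k] - inv[starts]) == 0L
    ids <- integer(length(starts))
    for (off in seq_len(k)) {
      ids <- ids * 4L + (code[starts + off - 1L] - 1L)
    }
    ids[!ok] <- NA_integer_
    sel <- !is.na(ids)
    agg_n <- tapply(rep(1L, sum(sel)), ids[sel], sum)
    agg_m <- tapply(muts[sel], ids[sel], sum)
    for (nm in names(agg_n)) {
      prev <- tallies[[nm]]
      if (is.null(prev)) prev <- c(0L, 0L)
      tallies[[nm]] <- prev + c(agg_n[[nm]], agg_m[[nm]])
    }
  }
  ids <- sort(as.integer(ls(tallies)))
  id_to_kmer <- function(id) {
    chars <- character(k)
    for (i in k:1) {
      chars[i] <- BASES[id %% 4L + 1L]
      id <- id %/% 4L
    }
    paste(chars, collapse = "")
  }
  do.call(rbind, lapply(ids, function(id) {
    v <- tallies[[as.character(id)]]
    data.frame(kmer = id_to_kmer(id), count = v[1L], mutations = v[2L],
               density = v[2L] / (v[1L] * (k - 1L)), stringsAsFactors = FALSE)
  }))
}

#' Reverse complement of a motif string
#' @param s ACGT string.
#' @return character scalar.
#' @export
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Strand-stratified motif density across predicted-rate deciles
#'
#' Motif instances (both strands) inside gene bodies are classified as
#' transcribed / non-transcribed by orientation relative to the gene's
#' strand, binned into deciles of the predicted mean rate over their
#' internal junctions, and the observed rare-variant density is computed
#' per bin per strand category.
#'
#' @param genome `genome` object.
#' @param motif ACGT motif string.
#' @param genes data.frame (contig, start, end, strand).
#' @param observed data.frame (contig, junction).
#' @param track data.frame (contig, junction, rate).
#' @param n_bins number of predicted-rate bins (default 10 deciles).
#' @return data.frame bin, strand_category, n, density.
#' @export
strand_stratified_density <- function(genome, motif, genes, observed, track,
                                      n_bins = 10L) {
  if (!all(genes$strand %in% c("+", "-"))) stop("strandless gene annotation")
  k <- nchar(motif)
  fwd <- kmer_occurrences(genome, motif)
  fwd$strand <- "+"
  rc <- revcomp(motif)
  rev_occ <- if (rc == motif) fwd[0, ] else {
    tmp <- kmer_occurrences(genome, rc)
    if (nrow(tmp)) tmp$strand <- "-"
    tmp
  }
  occ <- rbind(fwd, rev_occ)
  if (nrow(occ) == 0L) stop("motif absent from genome")
  # assign gene + orientation; instances outside genes are excluded
  occ$gene_strand <- NA_character_
  for (i in seq_len(nrow(genes))) {
    sel <- occ$contig == genes$contig[i] &
      occ$start1 >= genes$start[i] + 1L &
      occ$start1 + k - 1L <= genes$end[i]
    occ$gene_strand[sel] <- genes$strand[i]
  }
  occ <- occ[!is.na(occ$gene_strand), , drop = FALSE]
  if (nrow(occ) == 0L) stop("no motif instance inside gene bodies")
  occ$category <- ifelse(occ$strand == occ$gene_strand,
                         "transcribed", "non_transcribed")
  # predicted mean rate and observed density over internal junctions
  pred <- numeric(nrow(occ))
  dens <- numeric(nrow(occ))
  for (ctg in unique(occ$contig)) {
    sel <- which(occ$contig == ctg)
    tj <- track$junction[track$contig == ctg]
    tr <- track$rate[track$contig == ctg]
    ord <- order(tj)
    tj <- tj[ord]; tr <- tr[ord]
    cum_r <- c(0, cumsum(tr))
    jo <- sort(observed$junction[observed$contig == ctg])
    for (i in sel) {
      s <- occ$start1[i]
      lo <- findInterval(s - 1L, tj) + 1L
      hi <- findInterval(s + k - 2L, tj)
      pred[i] <- if (hi >= lo) (cum_r[hi + 1L] - cum_r[lo]) / (k - 1L) else 0
      lo2 <- findInterval(s - 1L, jo) + 1L
      hi2 <- findInterval(s + k - 2L, jo)
      dens[i] <- max(0L, hi2 - lo2 + 1L) / (k - 1L)
    }
  }
  occ$pred <- pred
  occ$dens <- dens
  qs <- quantile(occ$pred, probs = seq(0, 1, length.out = n_bins + 1L))
  occ$bin <- pmin(pmax(findInterval(occ$pred, qs, rightmost.closed = TRUE),
                       1L), n_bins)
  out <- expand.grid(bin = seq_len(n_bins),
                     strand_category = c("transcribed", "non_transcribed"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(b, sc) sum(occ$bin == b & occ$category == sc),
                  out$bin, out$strand_category)
  out$density <- mapply(function(b, sc) {
    sel <- occ$bin == b & occ$category == sc
    if (any(sel)) mean(occ$dens[sel]) else NA_real_
  }, out$bin, out$strand_category)
  attr(out, "instances") <- occ
  out
}

#' Meta-gene rate profile
#'
#' Averages a per-junction rate track over genes: a fixed upstream flank,
#' the gene body linearly rescaled to a common length, and a downstream
#' flank, all divided into bins. Minus-strand genes are flipped so profiles
#' read 5' to 3'.
#'
#' @param track data.frame (contig, junction, rate).
#' @param genes data.frame (contig, start, end, strand).
#' @param flank flank size (bp).
#' @param body_scaled common body length after rescaling (bp).
#' @param bin bin width (bp).
#' @return data.frame bin_start (coordinate in the meta-gene frame,
#'   0 = flank start), region (upstream/body/downstream), mean_rate.
#' @export
metagene_profile <- function(track, genes, flank = 3000L, body_scaled = 3000L,
                             bin = 50L) {
  stopifnot(nrow(genes) > 0)
  total <- 2L * flank + body_scaled
  n_bins <- total %/% bin
  acc <- numeric(n_bins)
  cnt <- numeric(n_bins)
  by_ctg <- split(track, track$contig)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tt <- by_ctg[[g$contig]]
    if (is.null(tt)) next
    glen <- g$end - g$start
    if (glen < 2L * bin) stop("gene shorter than 2 bins")
    j <- tt$junction
    r <- tt$rate
    # map junction to meta coordinate
    meta <- rep(NA_real_, length(j))
    up <- j >= g$start - flank & j < g$start
    meta[up] <- j[up] - (g$start - flank)
    body <- j >= g$start & j < g$end
    meta[body] <- flank + (j[body] - g$start) / glen * body_scaled
    dn <- j >= g$end & j < g$end + flank
    meta[dn] <- flank + body_scaled + (j[dn] - g$end)
    keep <- !is.na(meta)
    meta <- meta[keep]
    rr <- r[keep]
    if (g$strand == "-") meta <- total - meta - 1e-9
    bidx <- pmin(floor(meta / bin) + 1L, n_bins)
    for (b in unique(bidx)) {
      sel <- bidx == b
      acc[b] <- acc[b] + sum(rr[sel])
      cnt[b] <- cnt[b] + sum(sel)
    }
  }
  starts <- (seq_len(n_bins) - 1L) * bin
  region <- ifelse(starts < flank, "upstream",
                   ifelse(starts < flank + body_scaled, "body", "downstream"))
  data.frame(bin_start = starts, region = region,
             mean_rate = ifelse(cnt > 0, acc / cnt, NA_real_))
}
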