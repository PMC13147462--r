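# Rare-variant preparation: hypergeometric allele-count downsampling,
# singleton extraction, enumeration-based realignment, breakpoint
# decomposition, length binning, filtering and mutation-spectrum comparison.

#' Length-class binning scheme
#'
#' INDELs of 1..`max_individual` bp get their own class; lengths in
#' (`max_individual`, `pool_max`] are pooled into one class; longer events
#' are excluded. Defaults give seven classes: 1-6 bp individually, 7-20 bp
#' pooled as class 7.
#'
#' @param max_individual largest individually modeled length.
#' @param pool_max largest length retained at all.
#' @return a `length_binning` object with derived `n` (number of classes).
#' @export
length_binning <- function(max_individual = 6L, pool_max = 20L) {
  stopifnot(max_individual >= 1L, max_individual < pool_max)
  structure(list(max_individual = as.integer(max_individual),
                 pool_max = as.integer(pool_max),
                 n = as.integer(max_individual + 1L)),
            class = "length_binning")
}

#' Map an INDEL length to its class
#'
#' @param len integer vector of INDEL lengths (bp, >= 1).
#' @param binning a [length_binning()].
#' @return integer vector of classes; `NA` for lengths above `pool_max`
#'   (excluded).
#' @export
length_class <- function(len, binning = length_binning()) {
  if (any(len < 1L)) stop("INDEL length must be >= 1")
  cls <- ifelse(len <= binning$max_individual, len,
                ifelse(len <= binning$pool_max, binning$n, NA_integer_))
  as.integer(cls)
}

#' Hypergeometric downsampling of an alternate allele count
#'
#' Draws `AC_down ~ Hypergeometric(AN, AC, AN_down)`: the number of
#' alternate alleles in a without-replacement subsample of `AN_down`
#' haplotypes from a pool of `AN` carrying `AC` alternates.
#'
#' @param AN,AC original total and alternate allele counts (vectors recycle).
#' @param AN_down target total allele count.
#' @param rng_seed optional integer seed (scalar; set once for the batch).
#' @return integer vector of downsampled alternate counts.
#' @export
downsample_ac <- function(AN, AC, AN_down, rng_seed = NULL) {
  if (any(AC < 0) || any(AN < 0) || AN_down <= 0) stop("negative input")
  if (any(AC > AN)) stop("AC > AN")
  if (any(AN_down > AN)) stop("AN_down > AN")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  as.integer(stats::rhyper(max(length(AN), length(AC)), m = AC, n = AN - AC,
                           k = AN_down))
}

#' Extract rare (singleton) variants by downsampling
#'
#' Keeps variants whose downsampled alternate count equals 1; when several
#' qualifying alternates share one position, exactly one is kept at random.
#' Retained records carry AC = 1, AN = `AN_down`.
#'
#' @param variants data.frame of INDEL records with columns contig, pos1,
#'   ref, alt, AC, AN (see [read_indel_vcf()]).
#' @param AN_down downsampling target allele number.
#' @param rng_seed integer seed.
#' @return filtered data.frame.
#' @export
extract_rare <- function(variants, AN_down, rng_seed = 1L) {
  req <- c("contig", "pos1", "ref", "alt", "AC", "AN")
  if (!all(req %in% names(variants))) stop("record missing AC/AN fields")
  if (any(is.na(variants$AC)) || any(is.na(variants$AN))) {
    stop("record missing AC or AN")
  }
  set.seed(rng_seed)
  ac_down <- as.integer(stats::rhyper(nrow(variants), m = variants$AC,
                                      n = variants$AN - variants$AC,
                                      k = AN_down))
  keep <- variants[ac_down == 1L, , drop = FALSE]
  if (nrow(keep) > 1L) {
    key <- paste(keep$contig, keep$pos1)
    # uniform choice among duplicates at one position
    ord <- sample.int(nrow(keep))
    keep <- keep[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    keep <- keep[order(keep$contig, keep$pos1), , drop = FALSE]
  }
  keep$AC <- 1L
  keep$AN <- as.integer(AN_down)
  rownames(keep) <- NULL
  keep
}

classify_indel <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) stop("not a pure INDEL (equal allele lengths)")
  longer <- if (la > lr) alt else ref
  shorter <- if (la > lr) ref else alt
  if (substr(longer, 1L, nchar(shorter)) != shorter) {
    stop("not an anchor-base INDEL: ", ref, ">", alt)
  }
  list(kind = if (la > lr) "insertion" else "deletion",
       length = abs(la - lr))
}

#' Enumerate equivalent placements of an INDEL through flanking repeats
#'
#' Returns every anchor position at which the same event (identical
#' alternate haplotype) can be represented in VCF anchor-base form, sorted
#' by position. Placement q is valid when the reference prefix up to q and
#' the suffix after the event both match the alternate haplotype.
#'
#' @param genome `genome` object.
#' @param v one-row data.frame (contig, pos1, ref, alt, ...).
#' @return data.frame of equivalent records (one row per placement).
#' @export
enumerate_placements <- function(genome, v) {
  ctg <- genome[[v$contig]]
  if (is.null(ctg)) stop("contig absent: ", v$contig)
  info <- classify_indel(v$ref, v$alt)
  d <- info$length
  s <- ctg$seq
  n <- nchar(s)
  # search window: a shift of w requires a w-periodic tract; bound the scan
  # by the longest plausible repeat tract
  span <- d + 24L
  lo <- max(1L, v$pos1 - span)
  hi <- min(n, v$pos1 + span)
  if (info$kind == "deletion") {
    deleted <- substr(v$ref, 2L, d + 1L)
    if (substr(s, v$pos1 + 1L, v$pos1 + d) != deleted) {
      stop("ref allele does not match genome at ", v$contig, ":", v$pos1)
    }
    cand <- lo:hi
    ok <- vapply(cand, function(q) {
      q + d <= n && del_equivalent(s, v$pos1, q, d)
    }, logical(1))
    qs <- cand[ok]
    recs <- lapply(qs, function(q) {
      data.frame(contig = v$contig, pos1 = q,
                 ref = substr(s, q, q + d),
                 alt = substr(s, q, q),
                 stringsAsFactors = FALSE)
    })
  } else {
    ins <- substr(v$alt, 2L, d + 1L)
    cand <- lo:hi
    ok <- vapply(cand, function(q) ins_equivalent(s, v$pos1, ins, q),
                 logical(1))
    qs <- cand[ok]
    recs <- lapply(qs, function(q) {
      data.frame(contig = v$contig, pos1 = q,
                 ref = substr(s, q, q),
                 alt = paste0(substr(s, q, q), ins_at(s, v$pos1, ins, q)),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, recs)
  extra <- setdiff(names(v), names(out))
  for (col in extra) out[[col]] <- v[[col]]
  out[order(out$pos1), , drop = FALSE]
}

# deletion of s[p+1..p+d] equivalent to deletion of s[q+1..q+d]:
# the intervening sequence must be d-periodic
del_equivalent <- function(s, p, q, d) {
  if (q == p) return(TRUE)
  a <- min(p, q); b <- max(p, q)
  substr(s, a + 1L, b) == substr(s, a + d + 1L, b + d)
}

# insertion of `ins` after p representable after q: compare haplotypes.
# H = s[1..p] + ins + s[p+1..]; valid at q iff prefixes/suffixes line up.
ins_equivalent <- function(s, p, ins, q) {
  d <- nchar(ins)
  if (q == p) return(TRUE)
  if (q < p) {
    # need s[q+1..p] == H[q+1..p] trivially true; the inserted string at q
    # must be s[q+1..p]-rotated: check s[q+1 .. p] + ins == H segment
    # equivalently: s[q+1..q+d] (of H at q) ... compare directly:
    seg_h <- paste0(substr(s, q + 1L, p), ins)            # H[q+1 .. p+d]
    seg_q <- paste0(substr(s, q + 1L, q + 0L))            # ""
    # representable at q iff H[q+d+1 .. ] == s[q+1 .. ], i.e.
    # H[q+1..p+d] with first d chars removed equals s[q+1..p]
    substr(seg_h, d + 1L, nchar(seg_h)) == substr(s, q + 1L, p)
  } else {
    # q > p: need s[p+1..q] == H[p+1..q] = (ins + s[p+1..])[1..q-p]
    seg_h <- paste0(ins, substr(s, p + 1L, q))
    substr(seg_h, 1L, q - p) == substr(s, p + 1L, q)
  }
}

# the inserted string when the event is re-anchored at q
ins_at <- function(s, p, ins, q) {
  d <- nchar(ins)
  if (q == p) return(ins)
  if (q < p) {
    seg <- paste0(substr(s, q + 1L, p), ins)   # H[q+1 .. p+d]
    substr(seg, 1L, d)
  } else {
    seg <- paste0(ins, substr(s, p + 1L, q))   # H[p+1 .. q+d]
    substr(seg, q - p + 1L, q - p + d)
  }
}

#' Pick one placement uniformly at random
#' @param placements data.frame from [enumerate_placements()].
#' @param rng_seed integer seed.
#' @return one-row data.frame.
#' @export
assign_placement <- function(placements, rng_seed = 1L) {
  if (is.null(placements) || nrow(placements) == 0L) stop("empty placement list")
  set.seed(rng_seed)
  placements[sample.int(nrow(placements), 1L), , drop = FALSE]
}

#' Realign a set of variants and randomly assign placements
#'
#' Each variant gets a per-variant seeded stream derived from
#' `(global_seed, contig, left-aligned pos)` so results do not depend on
#' record order.
#'
#' @param genome `genome` object.
#' @param variants data.frame of INDEL records.
#' @param global_seed integer.
#' @return data.frame with reassigned pos1/ref/alt.
#' @export
realign_variants <- function(genome, variants, global_seed = 1L) {
  if (nrow(variants) == 0L) return(variants)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    pl <- enumerate_placements(genome, variants[i, , drop = FALSE])
    seed <- derive_seed(global_seed, variants$contig[i], pl$pos1[1L])
    assign_placement(pl, seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

derive_seed <- function(global_seed, contig, pos) {
  h <- sum(utf8ToInt(as.character(contig))) %% 7919L
  as.integer((as.numeric(global_seed) * 1000003 + h * 131 + as.numeric(pos) * 7)
             %% 2147483629)
}

#' Decompose INDELs into breakpoint sites
#'
#' An insertion yields one breakpoint at junction `pos1`; a deletion of
#' bases pos1+1..pos1+len yields a deletion-start junction at `pos1` and a
#' deletion-end junction at `pos1 + len`. Events longer than the pooling
#' maximum are dropped.
#'
#' @param variants data.frame of INDEL records.
#' @param binning a [length_binning()].
#' @return data.frame with columns contig, junction (0-based), kind
#'   (insertion / deletion_start / deletion_end), length, length_class.
#' @export
decompose_breakpoints <- function(variants, binning = length_binning()) {
  empty <- data.frame(contig = character(), junction = integer(),
                      kind = character(), length = integer(),
                      length_class = integer(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(empty)
  lr <- nchar(variants$ref); la <- nchar(variants$alt)
  if (any(lr == la)) stop("not a pure INDEL (equal allele lengths)")
  shorter <- ifelse(la > lr, variants$ref, variants$alt)
  longer <- ifelse(la > lr, variants$alt, variants$ref)
  if (any(substr(longer, 1L, nchar(shorter)) != shorter)) {
    stop("malformed ref/alt (not anchor-base INDELs)")
  }
  len <- abs(la - lr)
  kind <- ifelse(la > lr, "insertion", "deletion")
  cls <- length_class(len, binning)
  keep <- !is.na(cls)
  v <- variants[keep, , drop = FALSE]
  len <- len[keep]; kind <- kind[keep]; cls <- cls[keep]
  ins <- kind == "insertion"
  res <- rbind(
    data.frame(contig = v$contig[ins], junction = v$pos1[ins],
               kind = "insertion", length = len[ins],
               length_class = cls[ins], stringsAsFactors = FALSE),
    data.frame(contig = v$contig[!ins], junction = v$pos1[!ins],
               kind = "deletion_start", length = len[!ins],
               length_class = cls[!ins], stringsAsFactors = FALSE),
    data.frame(contig = v$contig[!ins], junction = v$pos1[!ins] + len[!ins],
               kind = "deletion_end", length = len[!ins],
               length_class = cls[!ins], stringsAsFactors = FALSE))
  res <- res[order(res$contig, res$junction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter breakpoint sites by coverage and excluded intervals
#'
#' Keeps sites whose two flanking bases both pass the coverage mask and
#' whose junction does not fall inside any excluded interval (e.g. exons).
#'
#' @param sites breakpoint data.frame (contig, junction, ...).
#' @param mask `coverage_mask`, or NULL to skip the coverage test.
#' @param excluded data.frame of intervals (contig, start, end), or NULL.
#' @return filtered data.frame.
#' @export
filter_sites <- function(sites, mask = NULL, excluded = NULL) {
  if (nrow(sites) == 0L) return(sites)
  keep <- rep(TRUE, nrow(sites))
  for (ctg in unique(sites$contig)) {
    sel <- sites$contig == ctg
    j <- sites$junction[sel]
    ok <- rep(TRUE, length(j))
    if (!is.null(mask)) {
      v <- mask[[ctg]]
      if (is.null(v)) {
        ok <- rep(FALSE, length(j))
      } else {
        n <- length(v)
        left_ok <- j >= 1L & j <= n & v[pmax(j, 1L)]
        right_ok <- j + 1L >= 1L & j + 1L <= n & v[pmin(j + 1L, n)]
        ok <- ifelse(j < 1L | j + 1L > n, FALSE, left_ok & right_ok)
      }
    }
    if (!is.null(excluded) && nrow(excluded)) {
      ok <- ok & !junction_in_intervals(ctg, j, excluded)
    }
    keep[sel] <- ok
  }
  sites[keep, , drop = FALSE]
}

#' Mutation spectrum of an INDEL set
#'
#' Length histogram over 1..pool_max, 2-mer junction-context histogram
#' (the base on each side of the variant's anchor junction), and the
#' insertion fraction.
#'
#' @param variants data.frame of INDEL records.
#' @param genome `genome` object.
#' @param binning a [length_binning()].
#' @return a `mutation_spectrum` (list of two named proportion vectors and
#'   `ins_del_ratio` = insertion fraction).
#' @export
spectrum <- function(variants, genome, binning = length_binning()) {
  if (nrow(variants) == 0L) stop("empty variant collection")
  lr <- nchar(variants$ref); la <- nchar(variants$alt)
  lens <- abs(la - lr)
  kinds <- ifelse(la > lr, "insertion", "deletion")
  lens <- pmin(lens, binning$pool_max)
  lh <- tabulate(lens, nbins = binning$pool_max)
  length_hist <- lh / sum(lh)
  names(length_hist) <- as.character(seq_len(binning$pool_max))
  twomers <- character(nrow(variants))
  for (ctg in unique(variants$contig)) {
    g <- genome[[ctg]]
    sel <- which(variants$contig == ctg)
    j <- variants$pos1[sel]
    a <- ifelse(j >= 1L & j <= g$length, substring(g$seq, j, j), "N")
    b <- ifelse(j + 1L <= g$length, substring(g$seq, j + 1L, j + 1L), "N")
    twomers[sel] <- paste0(a, b)
  }
  all2 <- as.vector(outer(BASES, BASES, paste0))
  ch <- table(factor(twomers, levels = all2))
  context_hist <- as.numeric(ch) / max(1, sum(ch))
  names(context_hist) <- all2
  structure(list(length_hist = length_hist, context_hist = context_hist,
                 ins_del_ratio = mean(kinds == "insertion")),
            class = "mutation_spectrum")
}

#' Distance between two mutation spectra
#'
#' Total variation distance averaged over the length and 2-mer histograms.
#' @param a,b `mutation_spectrum` objects.
#' @return numeric in `[0, 1]`.
#' @export
spectrum_distance <- function(a, b) {
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  mean(c(tv(a$length_hist, b$length_hist),
         tv(a$context_hist, b$context_hist)))
}

#' Read INDEL records from a VCF
#'
#' Keeps pure anchor-base INDELs; multi-allelic records are split into one
#' row per alternate. Requires INFO AC and AN.
#'
#' @param path VCF path (uncompressed or gzipped).
#' @return data.frame with contig, pos1, ref, alt, AC, AN, kind, length.
#' @export
read_indel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ac <- vcfR::extract.info(v, "AC")
  an <- suppressWarnings(as.integer(vcfR::extract.info(v, "AN")))
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  ac_list <- strsplit(ac, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_idx <- sequence(n_alt)
  out <- data.frame(
    contig = fix$CHROM[row_idx], pos1 = as.integer(fix$POS[row_idx]),
    ref = fix$REF[row_idx], alt = unlist(alt_list),
    AC = suppressWarnings(as.integer(mapply(
      function(i, k) if (k <= length(ac_list[[i]])) ac_list[[i]][k] else NA,
      row_idx, alt_idx))),
    AN = an[row_idx], stringsAsFactors = FALSE)
  # keep pure anchor-base INDELs
  lr <- nchar(out$ref); la <- nchar(out$alt)
  shorter <- ifelse(la > lr, out$ref, out$alt)
  longer <- ifelse(la > lr, out$alt, out$ref)
  pure <- lr != la & substr(longer, 1L, nchar(shorter)) == shorter
  out <- out[pure, , drop = FALSE]
  rownames(out) <- NULL
  info <- lapply(seq_len(nrow(out)),
                 function(i) classify_indel(out$ref[i], out$alt[i]))
  out$kind <- vapply(info, `[[`, "", "kind")
  out$length <- vapply(info, `[[`, 0L, "length")
  out
}

#' Write INDEL records as a minimal VCF 4.2
#' @param variants data.frame with contig, pos1, ref, alt, AC, AN.
#' @param path output path.
#' @export
write_indel_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(variants$contig, variants$pos1)
  v <- variants[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
                  v$contig, v$pos1, v$ref, v$alt, v$AC, v$AN)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write breakpoint sites as TSV
#' @param sites breakpoint data.frame.
#' @param path output path.
#' @export
write_breakpoints <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
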