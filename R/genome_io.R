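#' @importFrom stats rnorm runif rbinom rpois sd median quantile optim setNames
#' @importFrom utils head tail read.table write.table
NULL

BASES <- c("A", "C", "G", "T")

#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file, uppercases every sequence and maps any letter
#' outside A/C/G/T to N. Contigs are addressable by name.
#'
#' @param fasta_path path to a FASTA file.
#' @return An object of class `genome`: a named list of contigs, each a list
#'   with `name`, `seq` (character scalar over A,C,G,T,N), `length`, and
#'   `code` (integer vector, A=1 C=2 G=3 T=4, N/other=0) used by the
#'   encoding and simulation machinery.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) == 0L) stop("empty FASTA: ", fasta_path)
  nms <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nms)) stop("duplicate contig names in FASTA: ", fasta_path)
  contigs <- lapply(seq_along(dss), function(i) {
    s <- toupper(as.character(dss[[i]]))
    s <- gsub("[^ACGT]", "N", s)
    list(name = nms[i], seq = s, length = nchar(s), code = seq_to_code(s))
  })
  names(contigs) <- nms
  structure(contigs, class = "genome")
}

#' Build a genome object from in-memory sequences
#'
#' @param seqs named character vector of contig sequences.
#' @return A `genome` object (see [load_genome()]).
#' @export
genome_from_strings <- function(seqs) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate contig names")
  contigs <- lapply(names(seqs), function(nm) {
    s <- gsub("[^ACGT]", "N", toupper(seqs[[nm]]))
    list(name = nm, seq = s, length = nchar(s), code = seq_to_code(s))
  })
  names(contigs) <- names(seqs)
  structure(contigs, class = "genome")
}

#' Write a genome to FASTA
#' @param genome a `genome` object.
#' @param path output FASTA path.
#' @param width line width.
#' @export
write_genome <- function(genome, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(vapply(genome, `[[`, "", "seq"))
  names(dss) <- vapply(genome, `[[`, "", "name")
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

seq_to_code <- function(s) {
  raw <- charToRaw(s)
  code <- integer(length(raw))
  code[raw == charToRaw("A")] <- 1L
  code[raw == charToRaw("C")] <- 2L
  code[raw == charToRaw("G")] <- 3L
  code[raw == charToRaw("T")] <- 4L
  code
}

code_to_seq <- function(code) {
  chars <- c("N", "A", "C", "G", "T")[code + 1L]
  paste(chars, collapse = "")
}

#' Coverage mask from a bedGraph track
#'
#' A site passes iff `lo <= cov <= hi` with `lo = floor(mean_cov * (1 - frac))`
#' and `hi = floor(mean_cov * (1 + frac))` (closed bounds, floor on both).
#' With `mean_cov = 30.5, frac = 0.5` this yields the 15-45x window; with
#' `mean_cov = 113` it yields 56-169x.
#'
#' @param coverage either a path to a bedGraph file (contig, start0, end0,
#'   value) or a data.frame with those four columns. BED input with a value
#'   in the 4th column is accepted identically (0-based half-open).
#' @param genome `genome` object (defines contig bounds).
#' @param mean_cov mean coverage.
#' @param frac half-width of the retained band as a fraction of the mean.
#' @return A `coverage_mask`: named list of logical vectors, one per contig,
#'   `TRUE` at 1-based positions passing the filter, plus attributes
#'   `lo`/`hi`.
#' @export
build_coverage_mask <- function(coverage, genome, mean_cov, frac = 0.5) {
  stopifnot(frac > 0, frac < 1, mean_cov > 0)
  if (is.character(coverage)) {
    coverage <- read_bedgraph(coverage)
  }
  stopifnot(ncol(coverage) >= 4)
  names(coverage)[1:4] <- c("contig", "start", "end", "value")
  if (any(coverage$value < 0)) stop("negative coverage value")
  lo <- floor(mean_cov * (1 - frac))
  hi <- floor(mean_cov * (1 + frac))
  mask <- lapply(genome, function(ctg) {
    v <- rep(FALSE, ctg$length)
    rows <- coverage[coverage$contig == ctg$name, , drop = FALSE]
    if (nrow(rows)) {
      seen <- rep(NA_real_, ctg$length)
      for (i in seq_len(nrow(rows))) {
        a <- max(1L, rows$start[i] + 1L)
        b <- min(ctg$length, rows$end[i])
        if (a > b) next
        prev <- seen[a:b]
        if (any(!is.na(prev) & prev != rows$value[i])) {
          stop("overlapping coverage intervals with conflicting values on ",
               ctg$name)
        }
        seen[a:b] <- rows$value[i]
        v[a:b] <- rows$value[i] >= lo & rows$value[i] <= hi
      }
    }
    v
  })
  names(mask) <- names(genome)
  structure(mask, lo = lo, hi = hi, class = "coverage_mask")
}

read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("contig", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  if (any(df$end <= df$start)) stop("malformed bedGraph interval in ", path)
  df
}

#' Write a per-junction numeric track as bedGraph
#' @param track data.frame with columns contig, junction, value.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(track$contig, track$junction, track$junction + 1L,
                   track$value)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Junctions whose two flanking bases both pass a coverage mask
#'
#' Junction j0 (0-based, between 1-based bases j0 and j0+1) is eligible when
#' both flanking bases exist and pass; boundary junctions (j0 = 0 or
#' j0 = contig length) are never eligible.
#'
#' @param mask `coverage_mask`.
#' @param contig contig name.
#' @return integer vector of eligible junction indices.
#' @export
eligible_junctions <- function(mask, contig) {
  v <- mask[[contig]]
  if (is.null(v)) stop("contig absent from mask: ", contig)
  n <- length(v)
  which(v[-n] & v[-1])  # junction j0 = index into pairs (j0, j0+1)
}

#' One-hot encode a context window around a junction
#'
#' The window spans L/2 bases strictly upstream and L/2 strictly downstream
#' of junction `j0` (1-based bases j0-L/2+1 ... j0+L/2). N and out-of-contig
#' positions encode as all-zero columns. Row order is A, C, G, T.
#'
#' @param genome `genome` object.
#' @param contig contig name.
#' @param junction 0-based junction index in `[0, contig length]`.
#' @param L even window length (bp).
#' @return 4 x L numeric matrix.
#' @export
fetch_window <- function(genome, contig, junction, L) {
  arr <- encode_windows(genome, contig, junction, L)
  matrix(arr, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
}

#' Batch one-hot encoding of windows
#'
#' @inheritParams fetch_window
#' @param junctions integer vector of junction indices.
#' @return numeric array of dim (4, L, n_windows).
#' @export
encode_windows <- function(genome, contig, junctions, L) {
  if (L %% 2L != 0L || L < 2L) stop("window length L must be even and >= 2")
  ctg <- genome[[contig]]
  if (is.null(ctg)) stop("contig absent from genome: ", contig)
  if (any(junctions < 0L | junctions > ctg$length)) {
    stop("junction outside contig [0, ", ctg$length, "]")
  }
  B <- length(junctions)
  half <- L %/% 2L
  # 1-based genomic positions of the window columns, per window
  pos <- outer(seq_len(L) - half, junctions, `+`)  # L x B
  inside <- pos >= 1L & pos <= ctg$length
  codes <- integer(L * B)
  codes[inside] <- ctg$code[pos[inside]]
  out <- numeric(4L * L * B)
  nz <- which(codes > 0L)
  # linear index into (4, L, B): row codes[nz], column nz
  out[(nz - 1L) * 4L + codes[nz]] <- 1
  array(out, dim = c(4L, L, B))
}

#' Decode a one-hot window back to sequence
#' @param onehot 4 x L matrix (rows A,C,G,T); all-zero columns decode to N.
#' @return character scalar.
#' @export
decode_onehot <- function(onehot) {
  stopifnot(nrow(onehot) == 4L)
  idx <- apply(onehot, 2L, function(col) {
    w <- which(col == 1)
    if (length(w) == 1L) w else 0L
  })
  code_to_seq(as.integer(idx))
}

#' Read a BED file of intervals
#' @param path BED path (0-based half-open; columns contig, start, end, and
#'   optionally name, score, strand).
#' @return data.frame with contig, start, end (+ name, score, strand if
#'   present).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                   stringsAsFactors = FALSE)
  cols <- c("contig", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), length(cols)))]
  df$contig <- as.character(df$contig)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write intervals as BED
#' @param df data.frame with at least contig, start, end.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intervals as GRanges
#' @param df data.frame with contig, start (0-based), end, optional strand.
#' @return a [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
}

#' Does each junction fall inside any interval?
#'
#' A junction j0 lies inside interval [start, end) (0-based half-open) when
#' both flanking bases are within it, i.e. start + 1 <= j0 <= end - 1.
#' @param contig,junctions junction coordinates.
#' @param intervals data.frame with contig, start, end.
#' @return logical vector.
#' @export
junction_in_intervals <- function(contig, junctions, intervals) {
  hit <- rep(FALSE, length(junctions))
  rows <- intervals[intervals$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    hit <- hit | (junctions >= rows$start[i] + 1L & junctions <= rows$end[i] - 1L)
  }
  hit
}
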