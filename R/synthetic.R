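# Synthetic genomes, true rate maps and population cohorts with the
# statistical structure the framework assumes: homopolymer and dinucleotide
# repeats with length-dependent INDEL rates, a planted non-repeat hot motif
# boosting 1-bp insertions, and a neutral-like (1/a) allele-frequency
# spectrum. The generator is the oracle for parameter-recovery tests.

#' Synthetic genome specification
#'
#' Defaults are the study conditions used throughout the test-scale
#' analyses: 50% GC, ~2 homopolymer and ~1 dinucleotide run per kb, a
#' CTTACG hot motif (50x class-1 insertion rate at its internal junctions)
#' planted at ~0.5 occurrences per kb, base per-junction class-1 rates
#' 3e-5 (insertion) / 3.5e-5 (deletion) with geometric decay 0.55 per
#' class, homopolymer factor 2 per run base above 3 (the per-extra-base
#' fold change reported for 1-bp INDELs in mononucleotide runs), and
#' dinucleotide factor 1.6 per unit above 2. Rates saturate at `rate_cap`.
#'
#' @param n_contigs,contig_length genome shape.
#' @param gc_fraction GC content.
#' @param mono_per_kb,di_per_kb planted repeat densities (runs per kb).
#' @param motif planted hot motif (ACGT string).
#' @param motif_per_kb planted motif density.
#' @param motif_multiplier class-1 insertion rate multiplier inside the
#'   motif.
#' @param base_ins,base_del class-1 per-junction base rates.
#' @param class_decay geometric decay of base rate per length class.
#' @param f_mono per-extra-base homopolymer rate factor (class 1).
#' @param f_di per-extra-unit dinucleotide factor (class 2).
#' @param rate_cap saturation ceiling on any per-junction per-class rate
#'   (multipliers compound where repeats and motifs overlap).
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_contigs = 2L, contig_length = 1000000L,
                           gc_fraction = 0.5, mono_per_kb = 2,
                           di_per_kb = 1, motif = "CTTACG",
                           motif_per_kb = 0.5, motif_multiplier = 50,
                           base_ins = 3e-5, base_del = 3.5e-5,
                           class_decay = 0.55, f_mono = 2, f_di = 1.6,
                           rate_cap = 1e-3, seed = 1L) {
  stopifnot(motif_multiplier >= 1, grepl("^[ACGT]+$", motif))
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic genome
#'
#' Seeded and reproducible: iid background bases at the requested GC
#' fraction, overwritten with planted homopolymer runs (length 4 + Geom),
#' dinucleotide runs (3 + Geom units) and hot-motif occurrences on random
#' strands. Annotations are re-derived from the final sequence (string
#' scan), so chance occurrences count like planted ones.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome`, `motifs` (data.frame contig, start1, strand),
#'   `repeats` (from [simple_repeats()] with no flank).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  gc <- spec$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- list()
  for (ci in seq_len(spec$n_contigs)) {
    len <- spec$contig_length
    if (nchar(spec$motif) > len) stop("motif longer than contig")
    x <- sample(BASES, len, replace = TRUE, prob = probs)
    n_mono <- round(spec$mono_per_kb * len / 1000)
    if (n_mono > 0) {
      pos <- sample.int(len - 30L, n_mono)
      runlen <- 4L + stats::rgeom(n_mono, 0.45)
      runlen <- pmin(runlen, 12L)
      base <- sample(BASES, n_mono, replace = TRUE)
      for (i in seq_len(n_mono)) {
        x[pos[i]:(pos[i] + runlen[i] - 1L)] <- base[i]
      }
    }
    n_di <- round(spec$di_per_kb * len / 1000)
    if (n_di > 0) {
      pos <- sample.int(len - 40L, n_di)
      units <- 3L + stats::rgeom(n_di, 0.5)
      units <- pmin(units, 8L)
      for (i in seq_len(n_di)) {
        pair <- sample(BASES, 2L)
        x[pos[i]:(pos[i] + 2L * units[i] - 1L)] <- rep(pair, units[i])
      }
    }
    n_motif <- round(spec$motif_per_kb * len / 1000)
    if (n_motif > 0) {
      k <- nchar(spec$motif)
      pos <- sample.int(len - k - 10L, n_motif)
      strand <- sample(c("+", "-"), n_motif, replace = TRUE)
      for (i in seq_len(n_motif)) {
        s <- if (strand[i] == "+") spec$motif else revcomp(spec$motif)
        x[pos[i]:(pos[i] + k - 1L)] <- strsplit(s, "")[[1]]
      }
    }
    seqs[[paste0("ctg", ci)]] <- paste(x, collapse = "")
  }
  genome <- genome_from_strings(unlist(seqs))
  fwd <- kmer_occurrences(genome, spec$motif)
  if (nrow(fwd)) fwd$strand <- "+"
  motifs <- fwd
  rc <- revcomp(spec$motif)
  if (rc != spec$motif) {
    bwd <- kmer_occurrences(genome, rc)
    if (nrow(bwd)) {
      bwd$strand <- "-"
      motifs <- rbind(motifs, bwd)
    }
  }
  list(genome = genome, motifs = motifs,
       repeats = simple_repeats(genome, mono_min = 4L, di_min = 3L,
                                flank = 0L))
}

#' True generative rate map
#'
#' Class-c rate at junction j = base_rate_c x repeat multiplier x motif
#' multiplier. Homopolymer runs of length l >= 4 multiply class-1 rates by
#' `f_mono^(l - 3)` at internal junctions; dinucleotide runs of u >= 3
#' units multiply class-2 rates by `f_di^(u - 2)`; hot-motif internal
#' junctions multiply class-1 insertion rates by `motif_multiplier`.
#'
#' @param genome `genome` object.
#' @param spec a [synthetic_spec()].
#' @param motifs motif occurrence table from [generate_genome()].
#' @param binning a [length_binning()].
#' @return a `true_rate_map`: per contig, multiplier vectors over junctions
#'   0..len plus base-rate vectors; query with [true_rate()].
#' @export
true_rates <- function(genome, spec, motifs, binning = length_binning()) {
  n <- binning$n
  base_ins <- spec$base_ins * spec$class_decay^(0:(n - 1L))[1:n]
  base_del <- spec$base_del * spec$class_decay^(0:(n - 1L))[1:n]
  maps <- list()
  for (ctg in names(genome)) {
    code <- genome[[ctg]]$code
    len <- length(code)
    hp <- rep(1, len + 1L)   # index j0+1 for junction j0 in 0..len
    di <- rep(1, len + 1L)
    mo <- rep(1, len + 1L)
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values > 0L & r$lengths >= 4L)
    for (i in sel) {
      mult <- spec$f_mono^(r$lengths[i] - 3L)
      # internal junctions of run [s, e]: j0 = s .. e-1
      hp[(starts[i] + 1L):ends[i]] <- mult
    }
    # dinucleotide runs on the final sequence
    reps <- simple_repeats(genome[ctg], mono_min = 999L, di_min = 3L,
                           flank = 0L)
    reps <- reps[reps$contig == ctg & reps$type == "di", , drop = FALSE]
    for (i in seq_len(nrow(reps))) {
      u <- (reps$end[i] - reps$start[i]) %/% 2L
      mult <- spec$f_di^(max(0L, u - 2L))
      s1 <- reps$start[i] + 1L
      e1 <- reps$end[i]
      if (e1 > s1) di[(s1 + 1L):e1] <- mult
    }
    k <- nchar(spec$motif)
    mrows <- motifs[motifs$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(mrows))) {
      s1 <- mrows$start1[i]
      # internal junctions j0 = s1 .. s1+k-2
      mo[(s1 + 1L):(s1 + k - 1L)] <- spec$motif_multiplier
    }
    maps[[ctg]] <- list(hp = hp, di = di, mo = mo, len = len)
  }
  structure(list(contigs = maps, base_ins = base_ins, base_del = base_del,
                 n = n, binning = binning, motif = spec$motif,
                 rate_cap = spec$rate_cap),
            class = "true_rate_map")
}

#' Query the true rate map
#'
#' @param rates a `true_rate_map`.
#' @param contig contig name.
#' @param junctions junction indices (0-based).
#' @param kind "insertion" or "deletion_start".
#' @param class length class in 1..n, or "total" for the summed mutation
#'   rate over classes.
#' @return numeric vector of generative rates.
#' @export
true_rate <- function(rates, contig, junctions, kind = "insertion",
                      class = "total") {
  m <- rates$contigs[[contig]]
  if (is.null(m)) stop("contig absent from rate map")
  idx <- junctions + 1L
  base <- if (kind == "insertion") rates$base_ins else rates$base_del
  one_class <- function(cc) {
    mult <- rep(1, length(idx))
    if (cc == 1L) {
      mult <- m$hp[idx]
      if (kind == "insertion") mult <- mult * m$mo[idx]
    } else if (cc == 2L) {
      mult <- m$di[idx]
    }
    pmin(base[cc] * mult, rates$rate_cap)
  }
  if (identical(class, "total")) {
    Reduce(`+`, lapply(seq_len(rates$n), one_class))
  } else {
    one_class(as.integer(class))
  }
}

# draw allele counts from the truncated neutral spectrum P(AC = a) ~ 1/a
sample_sfs <- function(n, AN) {
  sample.int(AN, n, replace = TRUE, prob = 1 / seq_len(AN))
}

#' Simulate a population variant cohort
#'
#' Per junction, per class, per kind an event occurs with probability
#' `rate * event_scale`; allele counts follow the truncated 1/a spectrum.
#' Conflicting representations at one anchor position are resolved by
#' dropping the later event in seeded order. Events are restricted to
#' `eligible` junctions when given (e.g. the coverage mask).
#'
#' @param genome `genome` object.
#' @param rates a `true_rate_map`.
#' @param AN haplotype count of the cohort.
#' @param event_scale multiplier converting per-generation rates into
#'   per-cohort event probabilities (`event_scale * max rate` must be < 1).
#' @param seed integer seed.
#' @param eligible optional named list of eligible junction vectors.
#' @return data.frame of VCF-style records (contig, pos1, ref, alt, AC, AN,
#'   kind, length, true_junction).
#' @export
simulate_cohort <- function(genome, rates, AN = 2000L, event_scale = 100,
                            seed = 1L, eligible = NULL) {
  set.seed(seed)
  n <- rates$n
  binning <- rates$binning
  recs <- list()
  for (ctg in names(genome)) {
    code <- genome[[ctg]]$code
    s <- genome[[ctg]]$seq
    len <- length(code)
    ok_j <- if (!is.null(eligible)) eligible[[ctg]] else 1:(len - 1L)
    ok <- rep(FALSE, len + 1L)
    ok[ok_j + 1L] <- TRUE
    for (kind in c("insertion", "deletion")) {
      qkind <- if (kind == "insertion") "insertion" else "deletion_start"
      for (cc in seq_len(n)) {
        j_all <- 1:(len - 1L)
        p <- true_rate(rates, ctg, j_all, qkind, cc) * event_scale
        if (any(p >= 1)) stop("event_scale * rate >= 1")
        hit <- j_all[runif(len - 1L) < p & ok[j_all + 1L]]
        if (!length(hit)) next
        lens <- if (cc < binning$n) rep(cc, length(hit)) else
          sample(seq.int(binning$max_individual + 1L, binning$pool_max),
                 length(hit), replace = TRUE)
        anchor <- substring(s, hit, hit)
        if (kind == "insertion") {
          ins <- vapply(lens, function(ell) {
            paste(sample(BASES, ell, replace = TRUE), collapse = "")
          }, "")
          ref <- anchor
          alt <- paste0(anchor, ins)
          keep <- anchor != "N"
        } else {
          inb <- hit + lens <= len
          ref <- rep("N", length(hit))
          ref[inb] <- substring(s, hit[inb], hit[inb] + lens[inb])
          alt <- anchor
          keep <- inb & anchor != "N" & !grepl("N", ref, fixed = TRUE)
        }
        if (!any(keep)) next
        recs[[length(recs) + 1L]] <- data.frame(
          contig = ctg, pos1 = hit[keep], ref = ref[keep], alt = alt[keep],
          AC = 0L, AN = as.integer(AN), kind = kind,
          length = lens[keep], true_junction = hit[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(contig = character(), pos1 = integer(),
                      ref = character(), alt = character(), AC = integer(),
                      AN = integer(), kind = character(), length = integer(),
                      true_junction = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out$AC <- sample_sfs(nrow(out), AN)
  # drop later events at an already-used anchor (seeded order = build order)
  key <- paste(out$contig, out$pos1)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$contig, out$pos1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a blockwise coverage track
#'
#' Poisson coverage per `block` bp around `mean_cov`, with occasional
#' low-coverage (dropout) and high-coverage (collapsed-repeat) blocks so
#' the 15-45x style mask is non-trivial.
#'
#' @param genome `genome` object.
#' @param mean_cov mean coverage.
#' @param block block size (bp).
#' @param seed integer seed.
#' @return bedGraph-style data.frame (contig, start, end, value).
#' @export
simulate_coverage <- function(genome, mean_cov = 30, block = 100L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (ctg in names(genome)) {
    len <- genome[[ctg]]$length
    starts <- seq.int(0L, len - 1L, by = block)
    v <- rpois(length(starts), mean_cov)
    kind <- runif(length(starts))
    v[kind < 0.02] <- rpois(sum(kind < 0.02), mean_cov / 5)
    sel_hi <- kind > 0.98
    v[sel_hi] <- rpois(sum(sel_hi), mean_cov * 2.5)
    out[[ctg]] <- data.frame(contig = ctg, start = starts,
                             end = pmin(starts + block, len), value = v,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate gene/exon annotation
#'
#' Genes of 2-6 kb every ~`spacing` bp on alternating random strands; each
#' gene carries 2-4 exons. Used for exon masking and meta-gene profiles.
#'
#' @param genome `genome` object.
#' @param spacing mean gene spacing (bp).
#' @param seed integer seed.
#' @return list with `genes` and `exons` data.frames (contig, start, end,
#'   strand; 0-based half-open).
#' @export
simulate_genes <- function(genome, spacing = 20000L, seed = 1L) {
  set.seed(seed)
  genes <- list()
  exons <- list()
  for (ctg in names(genome)) {
    len <- genome[[ctg]]$length
    pos <- 5000L
    while (pos + 8000L < len - 5000L) {
      glen <- sample(2000:6000, 1L)
      strand <- sample(c("+", "-"), 1L)
      genes[[length(genes) + 1L]] <- data.frame(
        contig = ctg, start = pos, end = pos + glen, strand = strand,
        stringsAsFactors = FALSE)
      n_ex <- sample(2:4, 1L)
      bounds <- sort(sample(seq.int(100L, glen - 100L), 2L * n_ex))
      for (e in seq_len(n_ex)) {
        exons[[length(exons) + 1L]] <- data.frame(
          contig = ctg, start = pos + bounds[2L * e - 1L],
          end = pos + bounds[2L * e], strand = strand,
          stringsAsFactors = FALSE)
      }
      pos <- pos + glen + sample.int(2L * spacing, 1L)
    }
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Build a complete cross-consistent fixture
#'
#' tiny = 1 contig x 200 kb; standard = 2 contigs x 1 Mb. Writes FASTA,
#' VCF, coverage bedGraph, exon/gene BEDs, motif truth TSV and a JSON
#' manifest; returns the in-memory objects. Cohort events are restricted
#' to mask-passing junctions.
#'
#' @param preset "tiny" or "standard".
#' @param seed integer seed.
#' @param dir output directory (default: a fresh tempdir subdirectory).
#' @param event_scale cohort event-probability scale.
#' @return list with `genome`, `rates`, `cohort`, `mask`, `coverage`,
#'   `genes`, `exons`, `motifs`, `spec`, `dir` and file `paths`.
#' @export
fixture_bundle <- function(preset = c("tiny", "standard"), seed = 1L,
                           dir = NULL, event_scale = 700) {
  preset <- match.arg(preset)
  if (is.null(dir)) {
    dir <- file.path(tempfile(paste0("fixture_", preset, "_")))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (preset == "tiny") {
    synthetic_spec(n_contigs = 1L, contig_length = 200000L, seed = seed)
  } else {
    synthetic_spec(n_contigs = 2L, contig_length = 1000000L, seed = seed)
  }
  gen <- generate_genome(spec)
  genome <- gen$genome
  rates <- true_rates(genome, spec, gen$motifs)
  coverage <- simulate_coverage(genome, mean_cov = 30, seed = seed + 1L)
  mask <- build_coverage_mask(coverage, genome, mean_cov = 30.5, frac = 0.5)
  elig <- lapply(names(genome), function(ctg) eligible_junctions(mask, ctg))
  names(elig) <- names(genome)
  cohort <- simulate_cohort(genome, rates, AN = 2000L,
                            event_scale = event_scale, seed = seed + 2L,
                            eligible = elig)
  ann <- simulate_genes(genome, seed = seed + 3L)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "cohort.vcf"),
    coverage = file.path(dir, "coverage.bedGraph"),
    exons = file.path(dir, "exons.bed"),
    genes = file.path(dir, "genes.bed"),
    motifs = file.path(dir, "truth_motifs.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_genome(genome, paths$fasta)
  write_indel_vcf(cohort, paths$vcf)
  write.table(coverage, paths$coverage, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(ann$exons, paths$exons)
  write_bed(ann$genes, paths$genes)
  write.table(gen$motifs, paths$motifs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(preset = preset, seed = seed, event_scale = event_scale,
         spec = lapply(unclass(spec), function(v) v)),
    paths$manifest, auto_unbox = TRUE)
  list(genome = genome, rates = rates, cohort = cohort, mask = mask,
       coverage = coverage, genes = ann$genes, exons = ann$exons,
       motifs = gen$motifs, repeats = gen$repeats, spec = spec, dir = dir,
       paths = paths)
}
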