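# Attribution of predictions to input bases (integrated gradients and
# gradient x input), contribution profiles, seqlet extraction, PWM/CWM
# motif construction with information-content trimming, and the three
# motif-retention filters.

# gradient of the target-class logit (optionally the log-odds against
# class 0, the discriminative contrast) w.r.t. the input window(s)
input_gradient <- function(model, X, target_class, vs_class0 = FALSE) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  fwd <- unet_forward(model, X, train = FALSE, keep_cache = TRUE)
  B <- dim(X)[3L]
  dlogits <- matrix(0, model$cfg$n_classes + 1L, B)
  dlogits[target_class + 1L, ] <- 1
  if (vs_class0 && target_class != 0L) dlogits[1L, ] <- -1
  list(dX = unet_backward(model, fwd, dlogits)$dX, logits = fwd$logits)
}

#' Integrated gradients attribution
#'
#' Riemann-sum (midpoint) integrated gradients along the straight path from
#' `baseline` to the input, for the target-class logit. Satisfies the
#' completeness identity `sum(attributions) = F(input) - F(baseline)` up to
#' discretization error.
#'
#' @param model a `unet_model`.
#' @param window 4 x L one-hot matrix.
#' @param target_class integer in `[0, n]`.
#' @param steps number of path steps (>= 16).
#' @param baseline 4 x L matrix (default all zeros, the "absent sequence").
#' @param batch_steps how many path points to evaluate per forward pass.
#' @return 4 x L attribution matrix.
#' @export
integrated_gradients <- function(model, window, target_class, steps = 64L,
                                 baseline = NULL, batch_steps = 64L) {
  stopifnot(steps >= 16L)
  L <- model$cfg$L
  if (!all(dim(window) == c(4L, L))) stop("window shape mismatch")
  if (is.null(baseline)) baseline <- matrix(0, 4L, L)
  if (!all(dim(baseline) == c(4L, L))) stop("baseline shape mismatch")
  diff <- window - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  grad_sum <- matrix(0, 4L, L)
  for (s in seq.int(1L, steps, by = batch_steps)) {
    idx <- s:min(s + batch_steps - 1L, steps)
    X <- array(0, c(4L, L, length(idx)))
    for (i in seq_along(idx)) {
      X[, , i] <- baseline + alphas[idx[i]] * diff
    }
    g <- input_gradient(model, X, target_class)$dX
    grad_sum <- grad_sum + apply(g, c(1L, 2L), sum)
  }
  diff * grad_sum / steps
}

#' Gradient x input attribution
#'
#' Elementwise gradient of the target-class logit times the one-hot input;
#' exactly zero at N / padding columns.
#'
#' @inheritParams integrated_gradients
#' @return 4 x L attribution matrix.
#' @export
grad_x_input <- function(model, window, target_class) {
  g <- input_gradient(model, window, target_class)$dX[, , 1L]
  g * window
}

# batched grad x input for a set of windows: returns (4, L, B)
grad_x_input_batch <- function(model, X, target_class, vs_class0 = FALSE) {
  g <- input_gradient(model, X, target_class, vs_class0)$dX
  g * X
}

#' Per-position contribution profile of hypermutated vs control sites
#'
#' Position-wise mean absolute attribution over the central
#' `2 * half_width` bp for the high-rate site set and a control set, the
#' log-ratio profile, and optional z-score normalization.
#'
#' @param model a `unet_model`.
#' @param genome `genome` object.
#' @param hyper,control breakpoint data.frames (contig, junction).
#' @param target_class attribution target class.
#' @param half_width half-width of the central region (bp; default 100
#'   giving the central 200 bp).
#' @param zscore z-score normalize the log-ratio profile.
#' @param batch_size windows per forward/backward pass.
#' @return data.frame offset (junction-relative), mean_hyper, mean_control,
#'   log_ratio (optionally z-scored).
#' @export
contribution_profile <- function(model, genome, hyper, control, target_class,
                                 half_width = 100L, zscore = FALSE,
                                 batch_size = 64L) {
  if (nrow(hyper) == 0L || nrow(control) == 0L) stop("empty site set")
  L <- model$cfg$L
  if (half_width > L %/% 2L) stop("half_width exceeds window half-length")
  central <- (L %/% 2L - half_width + 1L):(L %/% 2L + half_width)
  mean_abs <- function(sites) {
    acc <- numeric(2L * half_width)
    n <- 0L
    starts <- seq.int(1L, nrow(sites), by = batch_size)
    for (s in starts) {
      rows <- sites[s:min(s + batch_size - 1L, nrow(sites)), , drop = FALSE]
      X <- encode_sites(genome, rows, L)
      A <- grad_x_input_batch(model, X, target_class)
      # per-position attribution = column sum over channels
      prof <- apply(abs(A[, central, , drop = FALSE]), c(2L, 3L), sum)
      acc <- acc + rowSums(prof)
      n <- n + nrow(rows)
    }
    acc / n
  }
  mh <- mean_abs(hyper)
  mc <- mean_abs(control)
  lr <- log((mh + 1e-12) / (mc + 1e-12))
  if (zscore) lr <- (lr - mean(lr)) / sd(lr)
  data.frame(offset = central - L %/% 2L, mean_hyper = mh, mean_control = mc,
             log_ratio = lr)
}

#' Extract seqlets from an attribution profile
#'
#' A simplified high-attribution seqlet extractor: maximal runs of the
#' smoothed per-position attribution magnitude above a quantile threshold,
#' merged across gaps <= `merge_gap`, clipped to the central region.
#' Magnitude is used because per-base contributions at informative
#' positions carry both signs; the signed values are preserved in the
#' contribution weight matrix downstream.
#'
#' @param attribution 4 x L attribution matrix for one window.
#' @param central width of the central region considered (bp).
#' @param threshold_quantile quantile (of positive central scores) above
#'   which a position is "high".
#' @param min_len minimum seqlet length.
#' @param merge_gap merge runs separated by at most this many positions.
#' @param smooth moving-average half-width for the per-position score.
#' @return data.frame offset_start, offset_end (window column indices),
#'   score (sum of per-position attribution).
#' @export
extract_seqlets <- function(attribution, central = 200L,
                            threshold_quantile = 0.9, min_len = 4L,
                            merge_gap = 2L, smooth = 1L) {
  L <- ncol(attribution)
  per_pos <- colSums(abs(attribution))
  lo <- max(1L, L %/% 2L - central %/% 2L + 1L)
  hi <- min(L, L %/% 2L + central %/% 2L)
  x <- per_pos[lo:hi]
  if (smooth > 0L) {
    kern <- rep(1 / (2L * smooth + 1L), 2L * smooth + 1L)
    x <- as.numeric(stats::filter(x, kern, sides = 2L))
    x[is.na(x)] <- 0
  }
  pos <- x[x > 0]
  if (!length(pos)) {
    return(data.frame(offset_start = integer(), offset_end = integer(),
                      score = numeric()))
  }
  thr <- quantile(pos, threshold_quantile)
  high <- x >= thr & x > 0
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(segs) == 0L) {
    return(data.frame(offset_start = integer(), offset_end = integer(),
                      score = numeric()))
  }
  merged <- segs[1L, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1L]) {
    if (segs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap) {
      merged$end[nrow(merged)] <- segs$end[i]
    } else {
      merged <- rbind(merged, segs[i, ])
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, , drop = FALSE]
  if (nrow(merged) == 0L) {
    return(data.frame(offset_start = integer(), offset_end = integer(),
                      score = numeric()))
  }
  data.frame(offset_start = merged$start + lo - 1L,
             offset_end = merged$end + lo - 1L,
             score = vapply(seq_len(nrow(merged)), function(i) {
               sum(per_pos[(merged$start[i] + lo - 1L):(merged$end[i] + lo - 1L)])
             }, 0))
}

# fixed-width seqlet centred on the attribution-magnitude peak
center_seqlet <- function(onehot, attribution, seg, width) {
  per_pos <- colSums(abs(attribution))
  rng <- seg$offset_start:seg$offset_end
  peak <- rng[which.max(per_pos[rng])]
  half <- width %/% 2L
  a <- peak - half + 1L
  b <- a + width - 1L
  if (a < 1L || b > ncol(onehot)) return(NULL)
  list(onehot = onehot[, a:b, drop = FALSE],
       attr = attribution[, a:b, drop = FALSE],
       score = seg$score)
}

#' Build a motif model from aligned seqlets
#'
#' PWM = column base frequencies of the seqlet one-hots; per-column
#' information content `IC = 2 - H2(column)` bits under a uniform
#' background; CWM = mean over seqlets of (one-hot x attribution);
#' contribution score = sum over CWM positions.
#'
#' @param seqlets list of seqlets (each with `onehot` and `attr` matrices
#'   of equal width).
#' @return a `motif_model` with `PWM`, `CWM`, `ic`, `n_seqlets`,
#'   `contribution`, `consensus`.
#' @export
build_motif <- function(seqlets) {
  stopifnot(length(seqlets) >= 1L)
  w <- ncol(seqlets[[1L]]$onehot)
  counts <- Reduce(`+`, lapply(seqlets, `[[`, "onehot"))
  PWM <- sweep(counts, 2L, pmax(colSums(counts), 1e-12), `/`)
  CWM <- Reduce(`+`, lapply(seqlets, function(s) s$onehot * s$attr)) /
    length(seqlets)
  ic <- apply(PWM, 2L, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
  rownames(PWM) <- rownames(CWM) <- BASES
  structure(list(PWM = PWM, CWM = CWM, ic = ic, n_seqlets = length(seqlets),
                 contribution = sum(CWM),
                 consensus = paste(BASES[apply(PWM, 2L, which.max)],
                                   collapse = "")),
            class = "motif_model")
}

#' Trim flank columns with information content below 0.1 bit
#' @param m a `motif_model`.
#' @return trimmed `motif_model` (errors if nothing remains).
#' @export
trim_motif <- function(m, ic_min = 0.1) {
  keep <- which(m$ic >= ic_min)
  if (!length(keep)) stop("width-0 motif after trimming")
  a <- min(keep); b <- max(keep)
  m$PWM <- m$PWM[, a:b, drop = FALSE]
  m$CWM <- m$CWM[, a:b, drop = FALSE]
  m$ic <- m$ic[a:b]
  m$contribution <- sum(m$CWM)
  m$consensus <- paste(BASES[apply(m$PWM, 2L, which.max)], collapse = "")
  m
}

# greedy star-alignment clustering of fixed-width seqlets (TF-MoDISco
# stand-in): seqlets join the best-matching cluster PWM over offsets
# within +/- max_shift, else seed a new cluster.
cluster_seqlets <- function(seqlets, max_shift = 4L, match_min = 0.6,
                            max_clusters = 20L) {
  ord <- order(-vapply(seqlets, `[[`, 0, "score"))
  clusters <- list()
  for (i in ord) {
    s <- seqlets[[i]]
    w <- ncol(s$onehot)
    best <- NULL
    for (ci in seq_along(clusters)) {
      pwm <- clusters[[ci]]$pwm
      for (shift in -max_shift:max_shift) {
        a <- max(1L, 1L + shift); b <- min(w, w + shift)
        cols_s <- (a - shift):(b - shift)
        sc <- mean(colSums(s$onehot[, cols_s, drop = FALSE] *
                             pwm[, a:b, drop = FALSE]))
        # mild penalty so a shifted motif core can still join its cluster
        penal <- sc * sqrt((b - a + 1L) / w)
        if (is.null(best) || penal > best$sc) {
          best <- list(ci = ci, shift = shift, sc = penal)
        }
      }
    }
    if (!is.null(best) && best$sc >= match_min) {
      cl <- clusters[[best$ci]]
      sh <- best$shift
      aligned <- shift_seqlet(s, sh)
      cl$members <- c(cl$members, list(aligned))
      counts <- Reduce(`+`, lapply(cl$members, `[[`, "onehot"))
      cl$pwm <- sweep(counts, 2L, pmax(colSums(counts), 1e-12), `/`)
      clusters[[best$ci]] <- cl
    } else if (length(clusters) < max_clusters) {
      pwm <- sweep(s$onehot, 2L, pmax(colSums(s$onehot), 1e-12), `/`)
      clusters[[length(clusters) + 1L]] <- list(pwm = pwm,
                                                members = list(s))
    }
  }
  clusters
}

# shift a seqlet by `shift` columns, zero-padding
shift_seqlet <- function(s, shift) {
  if (shift == 0L) return(s)
  w <- ncol(s$onehot)
  oh <- matrix(0, 4L, w); at <- matrix(0, 4L, w)
  if (shift > 0L) {
    oh[, (1L + shift):w] <- s$onehot[, 1L:(w - shift)]
    at[, (1L + shift):w] <- s$attr[, 1L:(w - shift)]
  } else {
    oh[, 1L:(w + shift)] <- s$onehot[, (1L - shift):w]
    at[, 1L:(w + shift)] <- s$attr[, (1L - shift):w]
  }
  s$onehot <- oh; s$attr <- at
  s
}

# integrated-gradients attribution of the target log-odds for one window
# (uniform 0.25 baseline = the average sequence, so signs express
# enrichment against background; midpoint rule, one batch over the path)
ig_window <- function(model, window, target_class, steps = 24L,
                      vs_class0 = TRUE) {
  L <- model$cfg$L
  base <- matrix(0.25, 4L, L)
  diffm <- window - base
  alphas <- (seq_len(steps) - 0.5) / steps
  X <- array(0, c(4L, L, steps))
  for (i in seq_len(steps)) X[, , i] <- base + alphas[i] * diffm
  g <- input_gradient(model, X, target_class, vs_class0)$dX
  diffm * apply(g, c(1L, 2L), mean)
}

#' Discover motifs from high-rate sites via attribution seqlets
#'
#' For each hypermutated site: integrated-gradients attribution of the
#' target-class log-odds (against class 0), seqlet extraction in the
#' central region, fixed-width peak-centred seqlets, greedy alignment
#' clustering, PWM/CWM construction and IC trimming. Integrated gradients
#' are used (rather than plain gradient x input) because motif responses
#' are AND-like and the local gradient at the input can miss or even
#' invert their contribution.
#'
#' @param model a `unet_model`.
#' @param genome `genome` object.
#' @param hyper data.frame (contig, junction) of high-rate sites.
#' @param target_class attribution target.
#' @param seqlet_width fixed seqlet width before trimming.
#' @param central central region width (bp).
#' @param min_seqlets clusters smaller than this are dropped.
#' @param batch_size windows per pass (gradient x input path; unused when
#'   `ig_steps > 0`).
#' @param ig_steps integrated-gradients path steps per window.
#' @param threshold_quantile passed to [extract_seqlets()].
#' @return list of trimmed `motif_model`s, largest cluster first.
#' @export
discover_motifs <- function(model, genome, hyper, target_class,
                            seqlet_width = 10L, central = 200L,
                            min_seqlets = 5L, batch_size = 64L,
                            ig_steps = 24L, threshold_quantile = 0.9) {
  L <- model$cfg$L
  seqlets <- list()
  for (i in seq_len(nrow(hyper))) {
    w <- fetch_window(genome, hyper$contig[i], hyper$junction[i], L)
    A <- if (ig_steps > 0L) {
      ig_window(model, w, target_class, steps = ig_steps)
    } else {
      grad_x_input_batch(model, array(w, c(4L, L, 1L)), target_class,
                         vs_class0 = TRUE)[, , 1L]
    }
    segs <- extract_seqlets(A, central = central,
                            threshold_quantile = threshold_quantile)
    for (r in seq_len(nrow(segs))) {
      sq <- center_seqlet(w, A, segs[r, ], seqlet_width)
      if (!is.null(sq)) seqlets[[length(seqlets) + 1L]] <- sq
    }
  }
  if (!length(seqlets)) return(list())
  clusters <- cluster_seqlets(seqlets)
  clusters <- clusters[vapply(clusters, function(cl) length(cl$members), 0L)
                       >= min_seqlets]
  if (!length(clusters)) return(list())
  ord <- order(-vapply(clusters, function(cl) length(cl$members), 0L))
  lapply(clusters[ord], function(cl) trim_motif(build_motif(cl$members)))
}

# reverse complement of a PWM/CWM-style 4 x w matrix (rows A,C,G,T)
revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- BASES
  out
}

# PWM occurrences on both strands (match score >= min_score of the maximum)
pwm_occurrences <- function(genome, pwm, min_score = "85%") {
  count_one <- function(p, subject) {
    length(Biostrings::matchPWM(p, subject, min.score = min_score))
  }
  tot <- 0L
  rc <- revcomp_pwm(pwm)
  palindromic <- isTRUE(all.equal(unname(pwm), unname(rc)))
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]]$seq)
    tot <- tot + count_one(pwm, subject)
    if (!palindromic) tot <- tot + count_one(rc, subject)
  }
  tot
}

#' Apply the three motif-retention filters
#'
#' Retains motifs passing all of: (i) the mean observed rare-variant
#' density at hyper sites whose central region matches the motif PWM is
#' higher than the mean over all hyper sites; (ii) the motif PWM matches
#' more than 100 positions in the genome, both strands (strict); (iii) the
#' motif contribution score is higher than the median over all candidate
#' motifs (strict). Occurrence and containment tests use PWM matching
#' (85% of the maximal score) rather than exact consensus strings, since
#' trimmed motifs are probabilistic.
#'
#' @param motifs list of `motif_model`s.
#' @param model a `unet_model` (defines the window length).
#' @param genome `genome` object.
#' @param hyper data.frame (contig, junction) of hypermutated sites.
#' @param observed data.frame (contig, junction) of observed variants.
#' @param central central region width (bp).
#' @param min_occurrences occurrence threshold (strict >).
#' @return list with `retained` (motifs) and `report` (per-motif criteria).
#' @export
filter_motifs <- function(motifs, model, genome, hyper, observed,
                          central = 200L, min_occurrences = 100L) {
  if (!length(motifs)) return(list(retained = list(), report = NULL))
  L <- model$cfg$L
  half <- central %/% 2L
  # observed density per hyper site over its central region
  site_density <- numeric(nrow(hyper))
  for (ctg in unique(hyper$contig)) {
    sel <- which(hyper$contig == ctg)
    jo <- sort(observed$junction[observed$contig == ctg])
    for (i in sel) {
      j0 <- hyper$junction[i]
      lo <- findInterval(j0 - half, jo) + 1L
      hi <- findInterval(j0 + half, jo)
      site_density[i] <- max(0L, hi - lo + 1L) / central
    }
  }
  overall_mean <- mean(site_density)
  # central sequences of hyper sites for consensus matching
  central_seqs <- vapply(seq_len(nrow(hyper)), function(i) {
    ctg <- genome[[hyper$contig[i]]]
    a <- max(1L, hyper$junction[i] - half + 1L)
    b <- min(ctg$length, hyper$junction[i] + half)
    substr(ctg$seq, a, b)
  }, "")
  contribs <- vapply(motifs, `[[`, 0, "contribution")
  med_contrib <- median(contribs)
  rows <- list()
  retained <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    cons <- m$consensus
    rc_pwm <- revcomp_pwm(m$PWM)
    has <- vapply(central_seqs, function(s) {
      subj <- Biostrings::DNAString(s)
      length(Biostrings::matchPWM(m$PWM, subj, min.score = "85%")) > 0L ||
        length(Biostrings::matchPWM(rc_pwm, subj, min.score = "85%")) > 0L
    }, TRUE, USE.NAMES = FALSE)
    c1 <- any(has) && mean(site_density[has]) > overall_mean
    occ <- pwm_occurrences(genome, m$PWM)
    c2 <- occ > min_occurrences
    c3 <- m$contribution > med_contrib
    rows[[mi]] <- data.frame(consensus = cons, n_seqlets = m$n_seqlets,
                             occurrences = occ,
                             contribution = m$contribution,
                             density_pass = c1, occurrence_pass = c2,
                             contribution_pass = c3,
                             retained = c1 && c2 && c3,
                             stringsAsFactors = FALSE)
    if (c1 && c2 && c3) retained[[length(retained) + 1L]] <- m
  }
  list(retained = retained, report = do.call(rbind, rows))
}

#' Annotate simple repeats (homopolymer and dinucleotide runs)
#'
#' Mononucleotide runs of length >= `mono_min` and dinucleotide repeats of
#' >= `di_min` units, with `flank` bp added on each side for exclusion.
#'
#' @param genome `genome` object.
#' @param mono_min minimum homopolymer run length (default 6).
#' @param di_min minimum dinucleotide unit count (default 3).
#' @param flank exclusion flank (bp, default 5).
#' @return data.frame contig, start, end (0-based half-open, flanks
#'   included), type.
#' @export
simple_repeats <- function(genome, mono_min = 6L, di_min = 3L, flank = 5L) {
  out <- list()
  for (ctg in names(genome)) {
    code <- genome[[ctg]]$code
    n <- length(code)
    # homopolymer runs
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts1 <- ends - r$lengths + 1L
    sel <- r$values > 0L & r$lengths >= mono_min
    mono <- data.frame(start1 = starts1[sel], end1 = ends[sel],
                       type = rep("mono", sum(sel)), stringsAsFactors = FALSE)
    # dinucleotide runs: positions where code[i] == code[i+2]
    di <- data.frame(start1 = integer(), end1 = integer(), type = character())
    if (n >= 2L * di_min) {
      same2 <- c(code[-(1:2)] == code[seq_len(n - 2L)] &
                   code[-(1:2)] > 0L, FALSE, FALSE)
      rr <- rle(same2)
      ee <- cumsum(rr$lengths)
      ss <- ee - rr$lengths + 1L
      keep <- rr$values & rr$lengths >= 2L * di_min - 2L
      if (any(keep)) {
        cand <- data.frame(start1 = ss[keep], end1 = ee[keep] + 2L)
        # require a true dinucleotide (two distinct bases), not homopolymer
        ok <- vapply(seq_len(nrow(cand)), function(i) {
          a <- code[cand$start1[i]]; b <- code[cand$start1[i] + 1L]
          a != b
        }, TRUE)
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand)) {
          di <- data.frame(start1 = cand$start1, end1 = cand$end1,
                           type = rep("di", nrow(cand)),
                           stringsAsFactors = FALSE)
        }
      }
    }
    both <- rbind(mono, di)
    if (nrow(both)) {
      out[[ctg]] <- data.frame(
        contig = ctg,
        start = pmax(0L, both$start1 - 1L - flank),
        end = pmin(n, both$end1 + flank),
        type = both$type, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), start = integer(),
                      end = integer(), type = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Export motifs in MEME minimal format
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    lines <- c(lines,
               sprintf("MOTIF %s motif_%d", m$consensus, i),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       ncol(m$PWM), m$n_seqlets),
               apply(t(m$PWM), 1L, function(row) {
                 paste(sprintf("%.6f", row), collapse = " ")
               }),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
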