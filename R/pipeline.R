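# High-level orchestration: from a population cohort to trained models and
# parameter-recovery metrics. These wrappers chain the module functions the
# way the full framework is meant to be run, at desk scale.

#' Rare-variant breakpoint preparation
#'
#' Downsample to singletons, realign through repeats, decompose into
#' breakpoints and filter by coverage (and optionally exons).
#'
#' @param genome `genome` object.
#' @param cohort data.frame of variant records (contig, pos1, ref, alt,
#'   AC, AN).
#' @param mask `coverage_mask`.
#' @param AN_down downsampling target allele count.
#' @param exons exon intervals to exclude (NULL keeps everything).
#' @param seed integer seed for downsampling and placement assignment.
#' @param binning a [length_binning()].
#' @return breakpoint data.frame (contig, junction, kind, length,
#'   length_class).
#' @export
prepare_breakpoints <- function(genome, cohort, mask, AN_down = 200L,
                                exons = NULL, seed = 1L,
                                binning = length_binning()) {
  rare <- extract_rare(cohort, AN_down = AN_down, rng_seed = seed)
  rare <- realign_variants(genome, rare, global_seed = seed + 1L)
  bps <- decompose_breakpoints(rare, binning)
  filter_sites(bps, mask, excluded = exons)
}

#' Default test-scale model and training configurations
#'
#' The compact configuration used for synthetic-genome experiments: 256-bp
#' windows, stride list (1,2,2,2,2,2), eight first-layer channels, a 64-bp
#' focal head crop; training at learning rate 3e-3 with stepwise decay.
#'
#' @param n_classes number of length classes.
#' @param seed training seed.
#' @param max_epochs epoch cap.
#' @return list with `model` ([model_config()]) and `train`
#'   ([train_config()]).
#' @export
test_scale_config <- function(n_classes = 7L, seed = 1L, max_epochs = 6L) {
  list(model = model_config(L = 256L,
                            stride_list = c(1L, 2L, 2L, 2L, 2L, 2L),
                            c0 = 8L, kernel_size = 5L,
                            n_classes = n_classes, head_crop = 64L),
       train = train_config(learning_rate = 3e-3, weight_decay = 1e-4,
                            lr_decay_factor = 0.5, lr_decay_every = 4L,
                            max_epochs = max_epochs, batch_size = 32L,
                            seed = seed))
}

#' Train a breakpoint model of one kind
#'
#' Samples class-0 junctions at `ratio_neg` per positive, builds the split
#' and trains.
#'
#' @param genome,mask genome and coverage mask.
#' @param breakpoints prepared breakpoint table.
#' @param kind breakpoint kind to model.
#' @param ratio_neg negatives per positive.
#' @param max_positives cap on the number of positives (uniform seeded
#'   subsample, as the full framework subsamples rare variants for
#'   training).
#' @param cfgs configuration pair from [test_scale_config()].
#' @param seed integer seed.
#' @return list with `checkpoint`, `trace`, `split`, `positives`.
#' @export
train_breakpoint_model <- function(genome, mask, breakpoints,
                                   kind = "insertion", ratio_neg = 1,
                                   max_positives = Inf,
                                   cfgs = test_scale_config(), seed = 1L) {
  pos <- breakpoints[breakpoints$kind == kind, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positives of kind ", kind)
  if (nrow(pos) > max_positives) {
    set.seed(seed + 5L)
    pos <- pos[sample(nrow(pos), max_positives), , drop = FALSE]
  }
  neg <- sample_negatives(genome, mask, pos,
                          count = round(ratio_neg * nrow(pos)),
                          seed = seed + 10L)
  split <- build_split(pos, neg, genome, L = cfgs$model$L,
                       val_frac = 1 / 6, seed = seed + 20L)
  tc <- cfgs$train
  tc$seed <- seed
  res <- train(cfgs$model, tc, split, genome)
  res$split <- split
  res$positives <- pos
  res
}

#' Parameter-recovery metrics against the true rate map
#'
#' Predicts on a seeded subsample of eligible junctions, aggregates
#' predicted and generative rates by k-mer, and reports the Pearson
#' correlation plus the top-decile odds ratio of planted hot-motif
#' junctions.
#'
#' @param model trained `unet_model`.
#' @param fixture a [fixture_bundle()] result.
#' @param kind breakpoint kind of the model.
#' @param k aggregation k-mer size (even).
#' @param n_per_contig junctions sampled per contig.
#' @param seed sampling seed.
#' @return list with `r_kmer`, `motif_or`, `agg` (per-k-mer table),
#'   `track`.
#' @export
recovery_metrics <- function(model, fixture, kind = "insertion", k = 4L,
                             n_per_contig = 30000L, seed = 1L) {
  set.seed(seed)
  g <- fixture$genome
  juncs <- lapply(names(g), function(ctg) {
    elig <- eligible_junctions(fixture$mask, ctg)
    sort(sample(elig, min(n_per_contig, length(elig))))
  })
  names(juncs) <- names(g)
  track <- predict_genome(model, g, junctions = juncs, batch_size = 512L)
  pcols <- grep("^p[1-9]", names(track), value = TRUE)
  # Poisson-corrected event rate (the pipeline's recurrence correction);
  # an affine scaling step would not change the correlations
  track$pred <- poisson_correct(as.matrix(track[, pcols, drop = FALSE]))$lambda
  track$truth <- unlist(lapply(names(juncs), function(ctg)
    true_rate(fixture$rates, ctg, juncs[[ctg]], kind, "total")))
  km <- unlist(lapply(names(juncs), function(ctg)
    junction_kmers(g, ctg, juncs[[ctg]], k)))
  ok <- !is.na(km)
  agg <- data.frame(
    pred = as.numeric(tapply(track$pred[ok], km[ok], mean)),
    truth = as.numeric(tapply(track$truth[ok], km[ok], mean)),
    row.names = names(tapply(track$pred[ok], km[ok], mean)))
  r <- stats::cor(agg$pred, agg$truth)
  hot <- unlist(lapply(names(juncs), function(ctg)
    fixture$rates$contigs[[ctg]]$mo[juncs[[ctg]] + 1L] > 1))
  top <- track$pred >= stats::quantile(track$pred, 0.9)
  tab <- table(factor(top, c(FALSE, TRUE)), factor(hot, c(FALSE, TRUE)))
  tab <- tab + 0.5   # Haldane-Anscombe correction: finite OR with empty cells
  motif_or <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  list(r_kmer = r, motif_or = motif_or, agg = agg, track = track)
}

#' Hypermutated and control site sets from a prediction track
#'
#' @param track prediction track with a `pred` column (see
#'   [recovery_metrics()]).
#' @param frac fraction of junctions taken as hypermutated (by predicted
#'   rate).
#' @param seed control-sampling seed.
#' @return list of data.frames `hyper` and `control` (equal sizes).
#' @export
hyper_control_sites <- function(track, frac = 0.005, seed = 1L) {
  n <- max(20L, round(nrow(track) * frac))
  ord <- order(-track$pred)
  hyper <- track[ord[seq_len(n)], c("contig", "junction")]
  set.seed(seed)
  rest <- track[-ord[seq_len(n)], c("contig", "junction")]
  control <- rest[sample(nrow(rest), n), ]
  rownames(hyper) <- rownames(control) <- NULL
  list(hyper = hyper, control = control)
}
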