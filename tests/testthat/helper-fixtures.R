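# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

tiny_fixture <- function() {
  cached("tiny", function() fixture_bundle("tiny", seed = 7L))
}

# a small trained binary model on the tiny fixture: class 1 = junction
# inside a homopolymer run, class 0 = background; used by the attribution
# and uncertainty tests
toy_model <- function() {
  cached("toy", function() {
    fx <- tiny_fixture()
    g <- fx$genome
    ctg <- names(g)[1L]
    hp <- fx$rates$contigs[[ctg]]$hp * fx$rates$contigs[[ctg]]$mo
    elig <- eligible_junctions(fx$mask, ctg)
    run_j <- elig[hp[elig + 1L] > 1]
    bg_j <- elig[hp[elig + 1L] == 1]
    set.seed(42)
    n <- 1200L
    pos <- data.frame(contig = ctg, junction = sample(run_j, n),
                      kind = "insertion", length_class = 1L,
                      stringsAsFactors = FALSE)
    neg <- data.frame(contig = ctg, junction = sample(bg_j, n),
                      kind = "none", length_class = 0L,
                      stringsAsFactors = FALSE)
    split <- build_split(pos, neg, g, L = 64L, val_frac = 0.1, seed = 1L)
    cfg <- model_config(L = 64L, stride_list = c(1L, 2L, 2L, 2L, 2L, 2L),
                        c0 = 4L, kernel_size = 5L, n_classes = 1L,
                        head_crop = 32L)
    tc <- train_config(learning_rate = 3e-3, weight_decay = 1e-4,
                       lr_decay_every = 3L, max_epochs = 4L,
                       batch_size = 64L, seed = 5L)
    res <- train(cfg, tc, split, g)
    list(model = res$checkpoint, fixture = fx, split = split, cfg = cfg)
  })
}

toy_cfg <- function() {
  model_config(L = 64L, stride_list = c(1L, 2L, 2L, 2L, 2L, 2L), c0 = 4L,
               kernel_size = 5L, n_classes = 2L, fc_width = 16L,
               head_crop = 32L)
}

random_simplex <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}

# the standard-fixture end-to-end experiment: rare-variant preparation,
# insertion-model training and recovery metrics; built once and shared by
# the acceptance checks
std_experiment <- function() {
  cached("std", function() {
    fx <- fixture_bundle("standard", seed = 1L)
    bps <- prepare_breakpoints(fx$genome, fx$cohort, fx$mask,
                               AN_down = 200L, exons = fx$exons, seed = 11L)
    cfgs <- test_scale_config(seed = 21L)
    fit <- train_breakpoint_model(fx$genome, fx$mask, bps,
                                  kind = "insertion", ratio_neg = 1,
                                  max_positives = 12000L, cfgs = cfgs,
                                  seed = 21L)
    met <- recovery_metrics(fit$checkpoint, fx, kind = "insertion", k = 4L,
                            n_per_contig = 25000L, seed = 31L)
    list(fx = fx, bps = bps, fit = fit, met = met, cfgs = cfgs)
  })
}
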