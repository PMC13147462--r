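# Training: cross-entropy loss, Adam with stepwise learning-rate decay,
# strict-minimum early stopping with patience 3, and lowest-validation-loss
# checkpoint selection across trials.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty applied to convolution / dense weights.
#' @param lr_decay_factor multiplicative decay factor in (0, 1].
#' @param lr_decay_every decay period in epochs.
#' @param max_epochs maximum epochs.
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping (default 3).
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling init and shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                         lr_decay_factor = 0.5, lr_decay_every = 2L,
                         max_epochs = 10L, patience = 3L, batch_size = 128L,
                         seed = 1L) {
  stopifnot(patience >= 1L, lr_decay_factor > 0, lr_decay_factor <= 1,
            max_epochs >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Mean cross-entropy of predictions against labels
#'
#' Computed from logits via log-softmax for numerical stability.
#'
#' @param logits (n+1) x B matrix (or a probability matrix with
#'   `from_probs = TRUE`).
#' @param labels integer labels in `[0, n]` (0 = no INDEL).
#' @param from_probs treat `logits` as probabilities.
#' @return mean negative log probability of the true class.
#' @export
cross_entropy <- function(logits, labels, from_probs = FALSE) {
  nc <- nrow(logits)
  if (any(labels < 0L) || any(labels > nc - 1L)) stop("label out of range")
  lp <- if (from_probs) log(pmax(logits, 1e-300)) else log_softmax_cols(logits)
  idx <- cbind(labels + 1L, seq_along(labels))
  -mean(lp[idx])
}

#' Early-stopping rule
#'
#' Stop iff the last `patience` epochs each failed to set a new strict
#' minimum over all prior epochs.
#'
#' @param val_losses numeric vector of validation losses so far.
#' @param patience integer.
#' @return logical.
#' @export
early_stop <- function(val_losses, patience = 3L) {
  n <- length(val_losses)
  if (n == 0L) stop("empty loss history")
  if (n <= patience) return(FALSE)
  running_min <- cummin(val_losses)
  # epoch t improves iff val_losses[t] < min(val_losses[1..t-1])
  improved <- c(TRUE, val_losses[-1L] < running_min[-n])
  all(!improved[(n - patience + 1L):n])
}

lr_at_epoch <- function(tc, epoch) {
  tc$learning_rate * tc$lr_decay_factor^((epoch - 1L) %/% tc$lr_decay_every)
}

eval_loss <- function(model, part, genome, L, batch_size = 256L) {
  total <- 0; n <- 0L
  starts <- seq.int(1L, nrow(part), by = batch_size)
  for (s in starts) {
    rows <- part[s:min(s + batch_size - 1L, nrow(part)), , drop = FALSE]
    X <- encode_sites(genome, rows, L)
    out <- unet_forward(model, X, train = FALSE, keep_cache = FALSE)
    total <- total + cross_entropy(out$logits, rows$label) * nrow(rows)
    n <- n + nrow(rows)
  }
  total / n
}

#' Train a model on a dataset split
#'
#' Adam with weight decay; the learning rate is multiplied by
#' `lr_decay_factor` every `lr_decay_every` epochs. Training stops at the
#' early-stopping rule or `max_epochs`, and the returned checkpoint is the
#' epoch with minimum validation loss. Fully deterministic given the seed.
#'
#' @param model_cfg a [model_config()].
#' @param tc a [train_config()].
#' @param split a `dataset_split` from [build_split()].
#' @param genome `genome` object.
#' @param val_loss_fn optional stub replacing validation-loss evaluation
#'   (takes the model and epoch, returns a number); used to script traces.
#' @param quiet suppress progress messages.
#' @return list with `checkpoint` (a `unet_model` with `val_loss`) and
#'   `trace` (data.frame epoch/train_loss/val_loss/lr plus `stopped_at`,
#'   `best_epoch` attributes).
#' @export
train <- function(model_cfg, tc, split, genome, val_loss_fn = NULL,
                  quiet = TRUE) {
  model <- init_model(model_cfg, seed = tc$seed)
  opt <- adam_init(model$params)
  best <- NULL
  best_loss <- Inf
  best_epoch <- NA_integer_
  trace <- list()
  val_losses <- numeric()
  for (epoch in seq_len(tc$max_epochs)) {
    lr <- lr_at_epoch(tc, epoch)
    batches <- iterate_batches(split$train, genome, split$L, tc$batch_size,
                               seed = tc$seed * 1000L + epoch)
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      fwd <- unet_forward(model, b$X, train = TRUE)
      loss <- cross_entropy(fwd$logits, b$y)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      Bn <- length(b$y)
      dlogits <- fwd$probs
      idx <- cbind(b$y + 1L, seq_len(Bn))
      dlogits[idx] <- dlogits[idx] - 1
      dlogits <- dlogits / Bn
      bwd <- unet_backward(model, fwd, dlogits)
      stepped <- adam_step(model$params, bwd$grads, opt, lr,
                           tc$weight_decay)
      model$params <- stepped$params
      opt <- stepped$state
      ep_loss <- ep_loss + loss * Bn
      ep_n <- ep_n + Bn
    }
    train_loss <- ep_loss / ep_n
    vl <- if (is.null(val_loss_fn)) {
      eval_loss(model, split$validation, genome, split$L)
    } else {
      val_loss_fn(model, epoch)
    }
    val_losses <- c(val_losses, vl)
    trace[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = vl, lr = lr)
    if (!quiet) {
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2e",
                      epoch, train_loss, vl, lr))
    }
    if (vl < best_loss) {
      best_loss <- vl
      best_epoch <- epoch
      best <- model
      best$params <- model$params
      best_bn <- as.list(model$bn)
    }
    if (early_stop(val_losses, tc$patience)) break
  }
  bn <- new.env(parent = emptyenv())
  for (k in names(best_bn)) bn[[k]] <- best_bn[[k]]
  best$bn <- bn
  best$val_loss <- best_loss
  best$train_cfg <- tc
  tr <- do.call(rbind, trace)
  attr(tr, "stopped_at") <- length(val_losses)
  attr(tr, "best_epoch") <- best_epoch
  list(checkpoint = best, trace = tr)
}

#' Run a seeded grid of training trials
#'
#' Sequential trials over (learning_rate, weight_decay); each trial applies
#' the early-stopping rule; the checkpoint with the global minimum
#' validation loss wins, ties broken by earlier grid order.
#'
#' @param model_cfg a [model_config()].
#' @param grid data.frame with columns learning_rate, weight_decay.
#' @param base_tc a [train_config()] supplying the remaining settings.
#' @param split,genome as in [train()].
#' @param val_loss_fn optional stub, passed through to [train()].
#' @return list with `checkpoint`, `trial` (winning row index), `losses`.
#' @export
grid_trials <- function(model_cfg, grid, base_tc, split, genome,
                        val_loss_fn = NULL) {
  stopifnot(nrow(grid) >= 1L)
  best <- NULL; best_loss <- Inf; best_trial <- NA_integer_
  losses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tc <- base_tc
    tc$learning_rate <- grid$learning_rate[i]
    tc$weight_decay <- grid$weight_decay[i]
    res <- tryCatch(
      train(model_cfg, tc, split, genome,
            val_loss_fn = if (is.null(val_loss_fn)) NULL else
              function(m, e) val_loss_fn(i, m, e)),
      error = function(e) NULL)
    losses[i] <- if (is.null(res)) Inf else res$checkpoint$val_loss
    if (!is.null(res) && res$checkpoint$val_loss < best_loss) {
      best_loss <- res$checkpoint$val_loss
      best <- res$checkpoint
      best_trial <- i
    }
  }
  if (is.null(best)) stop("all trials diverged")
  list(checkpoint = best, trial = best_trial, losses = losses)
}

#' Raw prediction track over all mask-passing junctions
#'
#' One probability vector per eligible junction, in genomic order.
#'
#' @param model a `unet_model`.
#' @param genome `genome` object.
#' @param mask `coverage_mask` (or NULL: all interior junctions).
#' @param batch_size inference batch size.
#' @param junctions optional named list (per contig) restricting the
#'   surveyed junctions.
#' @return data.frame with contig, junction, p0 ... pn.
#' @export
predict_genome <- function(model, genome, mask = NULL, batch_size = 256L,
                           junctions = NULL) {
  out <- list()
  for (ctg in names(genome)) {
    j <- if (!is.null(junctions)) {
      junctions[[ctg]]
    } else if (!is.null(mask)) {
      eligible_junctions(mask, ctg)
    } else {
      seq_len(genome[[ctg]]$length - 1L)
    }
    if (is.null(j) || !length(j)) next
    j <- sort(j)
    probs <- matrix(0, model$cfg$n_classes + 1L, length(j))
    starts <- seq.int(1L, length(j), by = batch_size)
    for (s in starts) {
      idx <- s:min(s + batch_size - 1L, length(j))
      X <- encode_windows(genome, ctg, j[idx], model$cfg$L)
      probs[, idx] <- predict_batch(model, X)
    }
    df <- data.frame(contig = ctg, junction = j, stringsAsFactors = FALSE)
    pm <- as.data.frame(t(probs))
    names(pm) <- paste0("p", 0:model$cfg$n_classes)
    out[[ctg]] <- cbind(df, pm)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
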