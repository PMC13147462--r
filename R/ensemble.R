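# Deep-ensemble prediction and epistemic uncertainty: ensemble-mean
# probabilities, entropy of the mean, and mutual information between the
# prediction and the member identity (natural-log entropy; MI = H[p_bar] -
# mean member entropy). Brier score support for MI-Brier correlation.

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Ensemble prediction with mutual-information uncertainty
#'
#' @param member_probs list of M probability vectors (or an M x (n+1)
#'   matrix, one member per row); members must share one architecture.
#' @return list with `p_bar`, `H_mean` (entropy of the mean), `MI`.
#' @export
ensemble_stats <- function(member_probs) {
  P <- if (is.list(member_probs)) do.call(rbind, member_probs) else member_probs
  M <- nrow(P)
  if (M < 2L) stop("ensemble requires M >= 2 members")
  p_bar <- colMeans(P)
  H_mean <- entropy_nat(p_bar)
  H_members <- apply(P, 1L, entropy_nat)
  list(p_bar = p_bar, H_mean = H_mean, MI = H_mean - mean(H_members))
}

#' Ensemble prediction for a batch of windows
#'
#' @param models list of M >= 2 `unet_model`s with identical configs
#'   (different random initializations).
#' @param X one-hot batch (4, L, B).
#' @return list with `p_bar` ((n+1) x B), `MI` (length B), `H_mean`.
#' @export
ensemble_predict <- function(models, X) {
  if (length(models) < 2L) stop("ensemble requires M >= 2 members")
  cfg0 <- unclass(models[[1L]]$cfg)
  for (m in models[-1L]) {
    if (!identical(unclass(m$cfg), cfg0)) stop("ensemble config mismatch")
  }
  preds <- lapply(models, function(m) predict_batch(m, X))  # (n+1) x B each
  M <- length(preds)
  p_bar <- Reduce(`+`, preds) / M
  ent <- function(P) -colSums(ifelse(P > 0, P * log(P), 0))
  H_mean <- ent(p_bar)
  H_members <- Reduce(`+`, lapply(preds, ent)) / M
  list(p_bar = p_bar, MI = H_mean - H_members, H_mean = H_mean)
}

#' Brier score of a probability vector against a label
#' @param p probability vector over classes 0..n.
#' @param label integer in `[0, n]`.
#' @return `sum_c (p_c - 1[c == label])^2`.
#' @export
brier <- function(p, label) {
  if (label < 0L || label > length(p) - 1L) stop("label out of range")
  y <- numeric(length(p))
  y[label + 1L] <- 1
  sum((p - y)^2)
}

#' Per-junction mutual-information track
#'
#' @param models list of M >= 2 `unet_model`s.
#' @param genome `genome` object.
#' @param mask `coverage_mask` (or NULL for all interior junctions).
#' @param batch_size inference batch size.
#' @param junctions optional per-contig junction list.
#' @return data.frame contig, junction, MI, plus mean-probability columns
#'   p0..pn.
#' @export
mi_track <- function(models, genome, mask = NULL, batch_size = 256L,
                     junctions = NULL) {
  if (length(models) < 2L) stop("ensemble requires M >= 2 members")
  out <- list()
  ncls <- models[[1L]]$cfg$n_classes
  for (ctg in names(genome)) {
    j <- if (!is.null(junctions)) junctions[[ctg]]
         else if (!is.null(mask)) eligible_junctions(mask, ctg)
         else seq_len(genome[[ctg]]$length - 1L)
    if (is.null(j) || !length(j)) next
    j <- sort(j)
    mi <- numeric(length(j))
    pb <- matrix(0, ncls + 1L, length(j))
    starts <- seq.int(1L, length(j), by = batch_size)
    for (s in starts) {
      idx <- s:min(s + batch_size - 1L, length(j))
      X <- encode_windows(genome, ctg, j[idx], models[[1L]]$cfg$L)
      ep <- ensemble_predict(models, X)
      mi[idx] <- ep$MI
      pb[, idx] <- ep$p_bar
    }
    df <- data.frame(contig = ctg, junction = j, MI = mi,
                     stringsAsFactors = FALSE)
    pm <- as.data.frame(t(pb))
    names(pm) <- paste0("p", 0:ncls)
    out[[ctg]] <- cbind(df, pm)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train an ensemble of independently initialized models
#'
#' @param model_cfg a [model_config()].
#' @param tc a [train_config()]; member m trains with seed `tc$seed + m`.
#' @param split,genome as in [train()].
#' @param M ensemble size (default 3).
#' @return list of M checkpoints.
#' @export
train_ensemble <- function(model_cfg, tc, split, genome, M = 3L) {
  stopifnot(M >= 2L, M <= 10L)
  lapply(seq_len(M), function(m) {
    tcm <- tc
    tcm$seed <- tc$seed + m
    train(model_cfg, tcm, split, genome)$checkpoint
  })
}
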