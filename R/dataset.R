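# Assembly of class-balanced training/validation sets of encoded examples
# from mutated and non-mutated junctions. Windows are one-hot encoded
# lazily, per batch, from the integer-coded genome; a split stores only the
# junction table and labels.

#' Sample non-mutated (class 0) junctions
#'
#' Uniform seeded sample of mask-passing junctions, excluding the positive
#' junctions.
#'
#' @param genome `genome` object.
#' @param mask `coverage_mask`.
#' @param positives breakpoint data.frame (contig, junction).
#' @param count number of negatives to draw.
#' @param seed integer seed.
#' @return data.frame (contig, junction, kind = "none", length_class = 0).
#' @export
sample_negatives <- function(genome, mask, positives, count, seed = 1L) {
  count <- as.integer(count)
  if (count == 0L) {
    return(data.frame(contig = character(), junction = integer(),
                      kind = character(), length_class = integer(),
                      stringsAsFactors = FALSE))
  }
  pool <- do.call(rbind, lapply(names(genome), function(ctg) {
    j <- eligible_junctions(mask, ctg)
    if (!length(j)) return(NULL)
    data.frame(contig = ctg, junction = j, stringsAsFactors = FALSE)
  }))
  if (is.null(pool)) stop("no eligible junctions")
  pos_key <- paste(positives$contig, positives$junction)
  pool <- pool[!(paste(pool$contig, pool$junction) %in% pos_key), ,
               drop = FALSE]
  if (nrow(pool) < count) stop("insufficient eligible junctions")
  set.seed(seed)
  sel <- pool[sample.int(nrow(pool), count), , drop = FALSE]
  sel$kind <- "none"
  sel$length_class <- 0L
  rownames(sel) <- NULL
  sel
}

#' Build a train/validation split
#'
#' Positives keep their length-class label; negatives are class 0. The
#' split is a deterministic seeded shuffle with the validation fraction
#' taken disjointly by junction (no junction appears in both partitions).
#' If two same-kind events of different classes map to one junction, one is
#' kept at random (seeded).
#'
#' @param positives,negatives breakpoint data.frames (contig, junction,
#'   length_class).
#' @param genome `genome` object (kept by reference for lazy encoding).
#' @param L window length.
#' @param val_frac validation fraction (of the total; validation size is
#'   `floor(n * val_frac)`).
#' @param seed integer seed.
#' @return a `dataset_split`: list with `train`, `validation` (data.frames
#'   with contig, junction, label), `L`, `ratio_neg_pos`, `seed`.
#' @export
build_split <- function(positives, negatives, genome, L, val_frac = 1 / 11,
                        seed = 1L) {
  stopifnot(L %% 2L == 0L, val_frac > 0, val_frac < 1)
  set.seed(seed)
  pos <- positives
  if (nrow(pos)) {
    key <- paste(pos$contig, pos$junction)
    if (anyDuplicated(key)) {
      ord <- sample.int(nrow(pos))
      pos <- pos[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    }
  }
  all <- rbind(
    data.frame(contig = pos$contig, junction = pos$junction,
               label = as.integer(pos$length_class), stringsAsFactors = FALSE),
    data.frame(contig = negatives$contig, junction = negatives$junction,
               label = 0L, stringsAsFactors = FALSE))
  key <- paste(all$contig, all$junction)
  if (anyDuplicated(key)) stop("duplicate junctions across pools")
  perm <- sample.int(nrow(all))
  all <- all[perm, , drop = FALSE]
  n_val <- floor(nrow(all) * val_frac)
  val <- all[seq_len(n_val), , drop = FALSE]
  train <- all[-seq_len(n_val), , drop = FALSE]
  rownames(val) <- rownames(train) <- NULL
  structure(list(train = train, validation = val, L = as.integer(L),
                 ratio_neg_pos = nrow(negatives) / max(1L, nrow(pos)),
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Iterate one epoch of seeded mini-batches
#'
#' Each epoch is a seeded permutation of the partition; every example
#' appears exactly once.
#'
#' @param part a partition data.frame from a `dataset_split`.
#' @param genome `genome` object.
#' @param L window length.
#' @param batch_size batch size (>= 1).
#' @param seed integer epoch seed.
#' @return list of batches, each `list(X = (4,L,b) array, y = integer labels)`.
#' @export
iterate_batches <- function(part, genome, L, batch_size, seed = 1L) {
  stopifnot(batch_size >= 1L)
  if (nrow(part) == 0L) stop("empty partition")
  set.seed(seed)
  ord <- sample.int(nrow(part))
  starts <- seq.int(1L, nrow(part), by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, nrow(part))]
    rows <- part[idx, , drop = FALSE]
    X <- encode_sites(genome, rows, L)
    list(X = X, y = rows$label)
  })
}

# one-hot encode a site table, batching per contig
encode_sites <- function(genome, rows, L) {
  B <- nrow(rows)
  X <- array(0, c(4L, L, B))
  for (ctg in unique(rows$contig)) {
    sel <- which(rows$contig == ctg)
    X[, , sel] <- encode_windows(genome, ctg, rows$junction[sel], L)
  }
  X
}

#' Serialize / restore a dataset split (TSV + JSON manifest)
#' @param split a `dataset_split`.
#' @param dir output directory.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(split$train, file.path(dir, "train.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(split$validation, file.path(dir, "validation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(L = split$L, ratio_neg_pos = split$ratio_neg_pos,
                            seed = split$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_split
#' @param dir directory written by [write_split()].
#' @export
read_split <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tr <- read.table(file.path(dir, "train.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  va <- read.table(file.path(dir, "validation.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  structure(list(train = tr, validation = va, L = as.integer(man$L),
                 ratio_neg_pos = man$ratio_neg_pos,
                 seed = as.integer(man$seed)),
            class = "dataset_split")
}
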