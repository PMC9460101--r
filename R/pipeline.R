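# Dataset splitting, stratified cross-validation folds, chunking, and the
# Adam training loop shared by all three architectures.

#' Train/validation vs test split
#'
#' Shuffles the utterance ids with the given seed and assigns the first
#' `floor(ratio * N)` to the train+validation pool, the remainder to the
#' test set. When labels are supplied the allocation is stratified by class
#' (largest-remainder rounding keeps the pool size exactly
#' `floor(ratio * N)`). There is no overlap between the two sets.
#'
#' @param ids Character or integer vector of unique utterance ids.
#' @param ratio Train+validation fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @param labels Optional per-id class labels for stratification.
#' @return A `split_plan` with `train_val_ids`, `test_ids`, `ratio`, `seed`.
#' @examples
#' length(split_dataset(as.character(1:1061), 0.8, 1)$train_val_ids)  # 848
#' @export
split_dataset <- function(ids, ratio = 0.8, seed = 1, labels = NULL) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  n_tv <- floor(ratio * length(ids))
  set.seed(seed)
  if (is.null(labels)) {
    sh <- sample(ids)
    tv <- sh[seq_len(n_tv)]
  } else {
    stopifnot(length(labels) == length(ids))
    classes <- unique(labels)
    base <- vapply(classes, function(cl) floor(ratio * sum(labels == cl)), 0)
    rem <- vapply(classes, function(cl) ratio * sum(labels == cl), 0) - base
    extra <- n_tv - sum(base)
    if (extra > 0) base[order(rem, decreasing = TRUE)[seq_len(extra)]] <-
        base[order(rem, decreasing = TRUE)[seq_len(extra)]] + 1
    tv <- unlist(lapply(seq_along(classes), function(i) {
      members <- sample(ids[labels == classes[i]])
      members[seq_len(base[i])]
    }))
  }
  structure(list(train_val_ids = tv, test_ids = setdiff(ids, tv),
                 ratio = ratio, seed = seed), class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class with the seed and deals its members onto the folds
#' round-robin, continuing the rotation across classes so overall fold sizes
#' stay within one of each other and per-class fold sizes differ by at most
#' one.
#'
#' @param ids Utterance ids of the train+validation pool.
#' @param labels Per-id class labels.
#' @param k Fold count (default 5).
#' @param seed Integer seed.
#' @return A `fold_plan` with `k` and `assignments` (named integer vector,
#'   id -> fold in 1..k).
#' @export
make_folds <- function(ids, labels, k = 5, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  stopifnot(length(ids) == length(labels))
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k members; smallest has ", min(tab))
  set.seed(seed)
  assignments <- integer(length(ids))
  names(assignments) <- ids
  offset <- 0L
  for (cl in names(tab)) {
    members <- sample(ids[labels == cl])
    assignments[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
    offset <- (offset + length(members)) %% k
  }
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_plan")
}

#' Cut a waveform into normalized chunks
#'
#' Sliding windows of `chunk_s` seconds at `shift_s` spacing; each chunk is
#' scaled to unit peak absolute amplitude (all-zero chunks pass through
#' unscaled). Chunk count is `floor((dur - chunk) / shift) + 1`.
#'
#' @param w A `labeled_waveform` (or list with `samples` and `sample_rate`).
#' @param chunk_s Chunk length in seconds.
#' @param shift_s Shift between chunk starts in seconds.
#' @return `chunk_len x n_chunks` numeric matrix, one normalized chunk per
#'   column.
#' @export
chunk_waveform <- function(w, chunk_s = 0.2, shift_s = 0.01) {
  fs <- w$sample_rate
  clen <- round(chunk_s * fs)
  shift <- max(1L, round(shift_s * fs))
  n <- length(w$samples)
  if (clen > n) stop("chunk longer than the utterance")
  starts <- seq.int(1L, n - clen + 1L, by = shift)
  out <- vapply(starts, function(s) {
    ch <- w$samples[s:(s + clen - 1L)]
    pk <- max(abs(ch))
    if (pk > 0) ch / pk else ch
  }, numeric(clen))
  matrix(out, nrow = clen)
}

# Stack the chunks of many utterances into one training array.
# Returns X (chunk_len, 1, N), integer labels y, utterance id per chunk.
build_chunkset <- function(waves, class_order, chunk_s, shift_s) {
  chunks <- lapply(waves, chunk_waveform, chunk_s = chunk_s, shift_s = shift_s)
  ncol_each <- vapply(chunks, ncol, 0L)
  X <- array(do.call(cbind, chunks), dim = c(nrow(chunks[[1]]), 1L, sum(ncol_each)))
  labs <- vapply(waves, `[[`, "", "label")
  ids <- vapply(waves, `[[`, "", "utterance_id")
  list(X = X,
       y = rep(match(labs, class_order), ncol_each),
       utt = rep(ids, ncol_each),
       class_order = class_order)
}

# Mean cross-entropy of a chunkset in inference mode, computed in batches.
dataset_loss <- function(model, cs, batch_size = 128) {
  n <- dim(cs$X)[3]
  tot <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- model_forward(model, cs$X[, , idx, drop = FALSE], training = FALSE)
    tot <- tot + xent_loss(fw$logits, cs$y[idx])$loss * length(idx)
  }
  tot / n
}

# Chunk posteriors for a whole chunkset: (n_classes x n_chunks) matrix.
dataset_posteriors <- function(model, cs, batch_size = 128) {
  n <- dim(cs$X)[3]
  out <- matrix(0, model$spec$n_classes, n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    out[, idx] <- predict_chunk_batch(model, cs$X[, , idx, drop = FALSE])
  }
  out
}

default_hyperparams <- function() {
  list(optimizer = "adam", lr = 1e-3, batch_size = 32L, epochs = 30L,
       patience = 5L)
}

#' Train one model on explicit train/validation chunk sets
#'
#' Runs minibatch Adam on chunk-level cross-entropy (utterance labels
#' broadcast to chunks), logging mean training loss and validation loss per
#' epoch, with early stopping on validation loss. All randomness (parameter
#' initialization, batch order, dropout masks) derives from `seed` through
#' the R random number generator, so runs are reproducible.
#'
#' @param spec A `network_spec`.
#' @param train_cs,val_cs Chunk sets from [build_chunkset()]; `val_cs` may be
#'   `NULL` (no early stopping).
#' @param hyperparams List overriding `lr`, `batch_size`, `epochs`,
#'   `patience`.
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return List with the best-validation `model` and a `state` list
#'   (`epoch_losses`, `val_losses`, `init_loss`, `best_epoch`, `seed`,
#'   `hyperparams`).
#' @export
fit_model <- function(spec, train_cs, val_cs = NULL,
                      hyperparams = list(), seed = 1, verbose = FALSE) {
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  set.seed(seed)
  model <- build_model(spec)
  model$class_order <- train_cs$class_order
  opt <- adam_new(model, lr = hp$lr)
  n <- dim(train_cs$X)[3]
  if (n == 0) stop("empty training fold")
  init_loss <- dataset_loss(model, train_cs)
  epoch_losses <- val_losses <- numeric(0)
  best <- list(model = model, val = Inf, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(hp$epochs)) {
    idx <- sample.int(n)
    batch_loss <- numeric(0)
    for (s in seq(1, n, by = hp$batch_size)) {
      bi <- idx[s:min(s + hp$batch_size - 1, n)]
      fw <- model_forward(model, train_cs$X[, , bi, drop = FALSE], training = TRUE)
      model <- fw$model
      ls <- xent_loss(fw$logits, train_cs$y[bi])
      if (!is.finite(ls$loss))
        stop("non-finite training loss at epoch ", ep,
             "; try a lower learning rate")
      grads <- model_backward(model, fw$caches, ls$glogits)
      st <- adam_step(model, grads, opt)
      model <- st$model; opt <- st$opt
      batch_loss <- c(batch_loss, ls$loss)
    }
    epoch_losses[ep] <- mean(batch_loss)
    if (!is.null(val_cs)) {
      val_losses[ep] <- dataset_loss(model, val_cs)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        epoch_losses[ep], val_losses[ep]))
      if (val_losses[ep] < best$val) {
        best <- list(model = model, val = val_losses[ep], epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hp$patience) break
      }
    } else {
      best <- list(model = model, val = NA_real_, epoch = ep)
      if (verbose) message(sprintf("epoch %d: train %.4f", ep, epoch_losses[ep]))
    }
  }
  list(model = best$model,
       state = list(epoch_losses = epoch_losses, val_losses = val_losses,
                    init_loss = init_loss, best_epoch = best$epoch,
                    seed = seed, hyperparams = hp))
}

#' Cross-validated training
#'
#' For each fold, trains on the remaining k-1 folds and validates on the
#' held-out fold, returning the best-validation model and training state per
#' fold. The fold seed is derived from `seed` so the whole procedure is
#' reproducible.
#'
#' @param spec A `network_spec`.
#' @param folds A `fold_plan` over the training pool.
#' @param waves List of `labeled_waveform`s (or a manifest data frame/path,
#'   loaded via [load_manifest()]) covering at least the fold ids.
#' @param class_order Label order defining the softmax head.
#' @param hyperparams See [fit_model()].
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(model, state)`.
#' @export
train <- function(spec, folds, waves, class_order = NULL,
                  hyperparams = list(), seed = 1) {
  if (is.character(waves) || is.data.frame(waves)) waves <- load_manifest(waves)
  ids <- vapply(waves, `[[`, "", "utterance_id")
  labs <- vapply(waves, `[[`, "", "label")
  if (is.null(class_order)) class_order <- sort(unique(labs))
  if (!all(labs %in% class_order)) stop("manifest labels outside the class order")
  lapply(seq_len(folds$k), function(f) {
    tr_ids <- names(folds$assignments)[folds$assignments != f]
    va_ids <- names(folds$assignments)[folds$assignments == f]
    if (length(va_ids) == 0) stop("empty validation fold ", f)
    tr <- build_chunkset(waves[ids %in% tr_ids], class_order,
                         spec$chunk_s, spec$shift_s)
    va <- build_chunkset(waves[ids %in% va_ids], class_order,
                         spec$chunk_s, spec$shift_s)
    fit_model(spec, tr, va, hyperparams, seed = seed + f)
  })
}
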