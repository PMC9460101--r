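# Utterance-level aggregation, confusion matrices, accuracy / per-class
# sensitivity / UAR metrics, and embedding collection for t-SNE maps.

#' Aggregate chunk posteriors into an utterance decision
#'
#' The utterance posterior is the arithmetic mean of the chunk posteriors;
#' the prediction is its argmax with the lowest class index winning ties.
#'
#' @param chunk_posteriors Matrix with one column per chunk (rows = classes)
#'   or list of posterior vectors.
#' @return List with `posterior` (mean vector) and `prediction` (class index,
#'   or label if the posteriors carry class names).
#' @export
aggregate_utterance <- function(chunk_posteriors) {
  if (is.list(chunk_posteriors))
    chunk_posteriors <- do.call(cbind, chunk_posteriors)
  if (is.null(dim(chunk_posteriors)))
    chunk_posteriors <- matrix(chunk_posteriors, ncol = 1)
  if (ncol(chunk_posteriors) == 0) stop("no chunks to aggregate")
  post <- rowMeans(chunk_posteriors)
  pred <- which.max(post)            # first maximum: lowest-index tie-break
  if (!is.null(names(post))) pred <- names(post)[pred]
  list(posterior = post, prediction = pred)
}

#' Utterance-level predictions for a set of waveforms
#'
#' Chunks each utterance with the model's configured chunk length and shift,
#' computes chunk posteriors in inference mode, and aggregates them with
#' [aggregate_utterance()].
#'
#' @param model A trained `voice_model` (with a `class_order`).
#' @param waves List of `labeled_waveform`s.
#' @return Data frame with `utterance_id`, `truth`, `prediction`; the
#'   utterance posterior matrix is attached as attribute `posteriors`.
#' @export
predict_utterances <- function(model, waves) {
  co <- model$class_order
  if (is.null(co)) stop("model has no class order; train it first")
  cs <- build_chunkset(waves, co, model$spec$chunk_s, model$spec$shift_s)
  post <- dataset_posteriors(model, cs)
  ids <- vapply(waves, `[[`, "", "utterance_id")
  agg <- vapply(ids, function(id)
    aggregate_utterance(post[, cs$utt == id, drop = FALSE])$posterior,
    numeric(length(co)))
  pred <- co[apply(agg, 2, which.max)]
  out <- data.frame(utterance_id = ids,
                    truth = vapply(waves, `[[`, "", "label"),
                    prediction = pred, stringsAsFactors = FALSE)
  attr(out, "posteriors") <- t(agg)
  out
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in `class_order`. The
#' row-normalized percentage matrix (each row summing to 100) is attached as
#' attribute `percent`, matching the count/percentage pairs shown in
#' confusion-matrix figures.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Label vector fixing row/column order.
#' @return A `confusion_matrix` (integer matrix with attributes).
#' @export
confusion <- function(true_labels, predicted_labels, class_order) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (!all(c(true_labels, predicted_labels) %in% class_order))
    stop("labels outside class_order")
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  counts <- unclass(table(truth = tf, prediction = pf))
  pct <- counts / pmax(rowSums(counts), 1L) * 100
  structure(counts, percent = pct, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `100 * trace / total`; per-class sensitivity (recall) is
#' `100 * cm[D, D] / rowsum(D)`; UAR is the arithmetic mean of the
#' sensitivities of the classes present. For binary detection with a
#' designated positive class, specificity is `100 * TN / (TN + FP)` on the
#' complementary class. Classes with no test samples are excluded from the
#' UAR with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @param positive_label Optional positive class for binary detection.
#' @return A `metrics_report` list: `accuracy`, `sensitivity_per_class`,
#'   `uar`, and `specificity` for binary detection. All values in percent.
#' @export
metrics <- function(cm, positive_label = NULL) {
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  rs <- rowSums(counts)
  sens <- 100 * diag(counts) / rs
  if (any(rs == 0)) {
    warning("class(es) with no test samples excluded from UAR: ",
            paste(rownames(counts)[rs == 0], collapse = ", "))
  }
  rep_ <- list(accuracy = 100 * sum(diag(counts)) / total,
               sensitivity_per_class = sens,
               uar = mean(sens[rs > 0]))
  if (!is.null(positive_label)) {
    if (nrow(counts) != 2) stop("positive_label requires a 2x2 matrix")
    neg <- setdiff(rownames(counts), positive_label)
    rep_$sensitivity <- sens[[positive_label]]
    rep_$specificity <- 100 * counts[neg, neg] / rs[[neg]]
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  UAR %.2f%%\n", x$accuracy, x$uar))
  for (nm in names(x$sensitivity_per_class))
    cat(sprintf("  sensitivity[%s] %.2f%%\n", nm, x$sensitivity_per_class[[nm]]))
  if (!is.null(x$specificity))
    cat(sprintf("  specificity %.2f%%\n", x$specificity))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  counts <- unclass(x)
  attr(counts, "percent") <- NULL
  print(counts)
  cat("row percentages:\n")
  print(round(attr(x, "percent"), 2))
  invisible(x)
}

#' Write a confusion matrix as CSV and optionally a heatmap PNG
#'
#' The CSV holds the raw counts (rows = true classes); the PNG shows the
#' row-normalized percentages with count/percentage pairs printed in each
#' cell, the layout used in confusion-matrix figures.
#'
#' @param cm A `confusion_matrix`.
#' @param csv_path Output CSV path.
#' @param png_path Optional heatmap PNG path.
#' @export
write_confusion <- function(cm, csv_path, png_path = NULL) {
  counts <- unclass(cm)
  attr(counts, "percent") <- NULL
  utils::write.csv(as.data.frame(counts), csv_path)
  if (!is.null(png_path)) {
    pct <- attr(cm, "percent")
    k <- nrow(counts)
    grDevices::png(png_path, width = 120 * k + 160, height = 120 * k + 120)
    graphics::par(mar = c(5, 5, 3, 1))
    graphics::image(seq_len(k), seq_len(k), t(pct[k:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(50, "Blues 3", rev = TRUE),
                    zlim = c(0, 100), axes = FALSE,
                    xlab = "predicted", ylab = "true", main = "confusion")
    graphics::axis(1, seq_len(k), colnames(counts))
    graphics::axis(2, seq_len(k), rev(rownames(counts)), las = 1)
    for (i in seq_len(k)) for (j in seq_len(k))
      graphics::text(j, k - i + 1, sprintf("%d\n%.1f%%", counts[i, j], pct[i, j]),
                     col = if (pct[i, j] > 50) "white" else "black")
    grDevices::dev.off()
  }
  invisible(csv_path)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` (or list of them, e.g. one per fold).
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean and standard deviation of metrics across folds
#'
#' @param reports List of `metrics_report`s, one per cross-validation fold.
#' @return Data frame with `metric`, `mean`, `sd` rows (accuracy, UAR and
#'   each per-class sensitivity), the `value +/- sd` presentation used for
#'   cross-validated results.
#' @export
summarize_folds <- function(reports) {
  grab <- function(r) c(accuracy = r$accuracy, uar = r$uar,
                        r$sensitivity_per_class)
  m <- do.call(rbind, lapply(reports, grab))
  data.frame(metric = colnames(m), mean = colMeans(m), sd = apply(m, 2, stats::sd),
             row.names = NULL)
}

#' Utterance-level embeddings
#'
#' The embedding of an utterance is the mean over its chunks of the
#' activation feeding the softmax head, computed with dropout off.
#'
#' @param model A trained `voice_model`.
#' @param waves List of `labeled_waveform`s.
#' @return List of class `embedding_table`: `utterance_id`, `label`, and an
#'   `n x d` `embeddings` matrix (one row per utterance).
#' @export
collect_embeddings <- function(model, waves) {
  co <- model$class_order
  if (is.null(co)) stop("model has no class order; train it first")
  cs <- build_chunkset(waves, co, model$spec$chunk_s, model$spec$shift_s)
  n <- dim(cs$X)[3]
  emb <- NULL
  for (s in seq(1, n, by = 128)) {
    idx <- s:min(s + 127, n)
    fw <- model_forward(model, cs$X[, , idx, drop = FALSE], training = FALSE)
    if (is.null(emb)) emb <- matrix(0, nrow(fw$embedding), n)
    emb[, idx] <- fw$embedding
  }
  ids <- vapply(waves, `[[`, "", "utterance_id")
  utt_emb <- t(vapply(ids, function(id)
    rowMeans(emb[, cs$utt == id, drop = FALSE]), numeric(nrow(emb))))
  structure(list(utterance_id = ids,
                 label = vapply(waves, `[[`, "", "label"),
                 embeddings = utt_emb),
            class = "embedding_table")
}

#' Two-dimensional t-SNE map of utterance embeddings
#'
#' Calls the Barnes-Hut t-SNE implementation (Rtsne) on the embedding rows.
#' Perplexity is clamped to `n/4` for small sets. The seed fixes the layout.
#'
#' @param emb An `embedding_table` from [collect_embeddings()].
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed Integer seed.
#' @param file Optional PNG path for a scatter plot colored by label.
#' @return Data frame with `utterance_id`, `label`, `x`, `y`.
#' @export
tsne_scatter <- function(emb, perplexity = 30, seed = 1, file = NULL) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("tsne_scatter requires the Rtsne package")
  n <- nrow(emb$embeddings)
  if (n < 3) stop("need at least 3 points for a t-SNE map")
  perp <- max(1, min(perplexity, floor(n / 4), floor((n - 1) / 3)))
  set.seed(seed)
  fit <- Rtsne::Rtsne(emb$embeddings, dims = 2, perplexity = perp,
                      check_duplicates = FALSE, pca = n > 50, verbose = FALSE)
  out <- data.frame(utterance_id = emb$utterance_id, label = emb$label,
                    x = fit$Y[, 1], y = fit$Y[, 2], stringsAsFactors = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 600)
    cls <- sort(unique(out$label))
    graphics::plot(out$x, out$y, col = match(out$label, cls), pch = 19,
                   xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "utterance embeddings")
    graphics::legend("topright", legend = cls, col = seq_along(cls), pch = 19)
    grDevices::dev.off()
  }
  out
}
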