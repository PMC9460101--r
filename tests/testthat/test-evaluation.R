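test_that("utterance aggregation averages posteriors with index tie-break", {
  one <- aggregate_utterance(matrix(c(0.2, 0.8), ncol = 1))
  expect_identical(one$prediction, 2L)
  tie <- aggregate_utterance(cbind(c(0.9, 0.1), c(0.1, 0.9)))
  expect_equal(tie$posterior, c(0.5, 0.5))
  expect_identical(tie$prediction, 1L)       # lowest class index wins ties
  named <- aggregate_utterance(matrix(c(0.3, 0.7), ncol = 1,
                                      dimnames = list(c("Normal", "Neo"))))
  expect_identical(named$prediction, "Neo")
  many <- aggregate_utterance(matrix(stats::runif(30), nrow = 3) |>
                                apply(2, function(p) p / sum(p)))
  expect_equal(sum(many$posterior), 1)
  expect_error(aggregate_utterance(matrix(numeric(0), nrow = 2)), "no chunks")
})

test_that("confusion matrices count and normalize correctly", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"), c("a", "b"))
  expect_identical(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 2L), 2,
                                           dimnames = dimnames(cm)))
  expect_equal(unname(rowSums(attr(cm, "percent"))), c(100, 100))
  perfect <- confusion(rep(c("a", "b", "c"), 5), rep(c("a", "b", "c"), 5),
                       c("a", "b", "c"))
  expect_true(all(unclass(perfect)[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion("a", "z", c("a", "b")), "outside")
})

test_that("metrics reproduce hand-counted examples", {
  ident <- confusion(rep(c("a", "b", "c"), each = 10),
                     rep(c("a", "b", "c"), each = 10), c("a", "b", "c"))
  m <- metrics(ident)
  expect_equal(m$accuracy, 100)
  expect_equal(m$uar, 100)

  # binary detection, rows ordered [negative, positive]
  bin <- confusion(rep(c("neg", "pos"), each = 10),
                   c(rep("neg", 7), rep("pos", 3), rep("neg", 2), rep("pos", 8)),
                   c("neg", "pos"))
  mb <- metrics(bin, positive_label = "pos")
  expect_equal(mb$accuracy, 75.0)
  expect_equal(mb$sensitivity, 80.0)
  expect_equal(mb$specificity, 70.0)

  # UAR is the unweighted mean of per-class sensitivities
  tri <- confusion(rep(c("a", "b", "c"), each = 10),
                   c(rep("a", 6), rep("b", 4),
                     rep("b", 7), rep("c", 3),
                     rep("c", 8), rep("a", 2)), c("a", "b", "c"))
  mt <- metrics(tri)
  expect_equal(unname(mt$sensitivity_per_class), c(60, 70, 80))
  expect_equal(mt$uar, 70.0)
})

test_that("metrics match brute-force TP/TN/FP/FN counting", {
  set.seed(123)
  worst <- 0
  for (i in seq_len(1000)) {
    k <- sample(2:4, 1)
    classes <- letters[seq_len(k)]
    n <- sample(5:200, 1)
    truth <- sample(classes, n, replace = TRUE)
    while (length(unique(truth)) < k) truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- metrics(confusion(truth, pred, classes))
    acc_bf <- 100 * mean(truth == pred)
    sens_bf <- vapply(classes, function(cl) {
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      100 * tp / (tp + fn)
    }, 0)
    worst <- max(worst, abs(m$accuracy - acc_bf),
                 abs(m$sensitivity_per_class - sens_bf),
                 abs(m$uar - mean(sens_bf)))
  }
  expect_lt(worst, 1e-9)
})

test_that("UAR equals accuracy on balanced confusion matrices", {
  set.seed(77)
  worst <- 0
  for (i in seq_len(200)) {
    k <- sample(2:4, 1)
    per <- sample(3:30, 1)
    classes <- letters[seq_len(k)]
    truth <- rep(classes, each = per)
    pred <- sample(classes, k * per, replace = TRUE)
    m <- metrics(confusion(truth, pred, classes))
    worst <- max(worst, abs(m$uar - m$accuracy))
  }
  expect_lt(worst, 1e-9)
})

test_that("classes absent from the test set are excluded with a warning", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b", "c"))
  expect_warning(m <- metrics(cm), "excluded")
  expect_equal(m$uar, mean(c(50, 100)))
})

test_that("utterance predictions and embeddings are one row per utterance", {
  fx <- fx_twoclass()
  set.seed(6)
  m <- build_model(compact_sincnet_spec(2))
  m$class_order <- fx$classes
  pu <- predict_utterances(m, fx$waves)
  expect_identical(nrow(pu), length(fx$waves))
  expect_true(all(pu$prediction %in% fx$classes))
  post <- attr(pu, "posteriors")
  expect_equal(unname(rowSums(post)), rep(1, nrow(pu)), tolerance = 1e-9)

  emb <- collect_embeddings(m, fx$waves)
  expect_identical(nrow(emb$embeddings), length(fx$waves))
  expect_identical(ncol(emb$embeddings), 48L)   # last FC width of the compact net
  # identical audio yields identical embeddings
  dup <- fx$waves[[1]]
  dup$utterance_id <- "copy"
  emb2 <- collect_embeddings(m, list(fx$waves[[1]], dup))
  expect_equal(emb2$embeddings[1, ], emb2$embeddings[2, ], tolerance = 1e-12)
})

test_that("confusion matrices export consistent CSV counts and heatmaps", {
  cm <- confusion(rep(c("a", "b"), each = 10),
                  c(rep("a", 7), rep("b", 3), rep("b", 9), "a"), c("a", "b"))
  csv <- withr::local_tempfile(fileext = ".csv")
  png <- withr::local_tempfile(fileext = ".png")
  write_confusion(cm, csv, png)
  back <- utils::read.csv(csv, row.names = 1)
  expect_equal(unname(as.matrix(back)), unclass(cm)[, ], ignore_attr = TRUE)
  expect_gt(file.size(png), 0)
  # printed percentages are consistent with the counts
  pct <- attr(cm, "percent")
  expect_equal(pct, unclass(cm) / rowSums(unclass(cm)) * 100,
               ignore_attr = TRUE)
})

test_that("t-SNE maps keep separated classes separated", {
  skip_if_not_installed("Rtsne")
  set.seed(42)
  emb <- structure(list(
    utterance_id = sprintf("u%02d", 1:40),
    label = rep(c("a", "b"), each = 20),
    embeddings = rbind(matrix(stats::rnorm(20 * 10), 20),
                       matrix(stats::rnorm(20 * 10, mean = 8), 20))),
    class = "embedding_table")
  out <- tsne_scatter(emb, perplexity = 30, seed = 1)   # clamped internally
  expect_identical(nrow(out), 40L)
  out2 <- tsne_scatter(emb, perplexity = 30, seed = 1)
  expect_identical(out$x, out2$x)
  xy <- as.matrix(out[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  same <- outer(out$label, out$label, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
  expect_error(tsne_scatter(structure(list(utterance_id = "a", label = "a",
                                           embeddings = matrix(1, 1)),
                                      class = "embedding_table")),
               "at least 3")
})
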