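test_that("reference architectures encode the documented configuration", {
  sp <- default_sincnet_spec(4, 16000)
  expect_identical(sp$front_end$type, "sinc")
  expect_identical(sp$front_end$n_filters, 80L)
  expect_identical(sp$front_end$filter_len, 251L)
  expect_identical(vapply(sp$conv_layers, `[`, 0L, 1), c(60L, 60L))
  expect_identical(vapply(sp$conv_layers, `[`, 0L, 2), c(5L, 5L))
  expect_identical(sp$fc_layers, c(2048L, 2048L, 2048L))
  expect_equal(sp$dropout_conv, 0.5)
  expect_equal(sp$dropout_fc, c(0.3, 0.3, 0.3))

  c2 <- default_cnn2d_spec(4, 16000)
  expect_identical(vapply(c2$conv_layers, `[[`, 0L, "channels"),
                   c(80L, 60L, 60L))
  expect_equal(c2$dropout_fc, c(0.3, 0.2, 0.2))
  expect_identical(c2$front_end$type, "conv2d-spectrogram")

  expect_error(default_sincnet_spec(1, 16000), "at least 2")
  expect_error(network_spec(sp$front_end, sp$conv_layers, 3L, c(8L),
                            dropout_conv = 1.2, dropout_fc = 0,
                            n_classes = 2, sample_rate = 16000),
               "dropout")
})

test_that("sinc and 1-D baseline specs differ only in the front end", {
  a <- default_sincnet_spec(4, 16000)
  b <- default_cnn1d_spec(4, 16000)
  a$front_end <- NULL
  b$front_end <- NULL
  expect_identical(yaml::as.yaml(unclass(a)), yaml::as.yaml(unclass(b)))
  x <- compact_sincnet_spec(4)
  y <- compact_cnn1d_spec(4)
  x$front_end <- NULL
  y$front_end <- NULL
  expect_identical(x, y)
})

test_that("spec serialization round-trips through YAML", {
  sp <- compact_sincnet_spec(3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(sp, path)
  sp2 <- read_network_spec(path)
  expect_equal(sp2$fc_layers, sp$fc_layers)
  expect_equal(sp2$front_end$n_filters, sp$front_end$n_filters)
  expect_s3_class(sp2, "network_spec")
})

test_that("built models match the symbolic parameter count", {
  for (sp in list(compact_sincnet_spec(4), compact_cnn1d_spec(2),
                  default_cnn2d_spec(3, 16000))) {
    set.seed(1)
    m <- build_model(sp)
    expect_identical(count_params(m), spec_param_count(sp))
  }
})

test_that("the reference sinc model has a 160-scalar front end and 2048-wide embedding", {
  set.seed(1)
  m <- build_model(default_sincnet_spec(4, 16000))
  expect_identical(count_params(m, front_only = TRUE), 160L)
  expect_identical(count_params(m), spec_param_count(default_sincnet_spec(4, 16000)))
  chunk <- sin(2 * pi * 200 * seq_len(m$chunk_len) / 16000)
  emb <- extract_embedding(m, chunk)
  expect_length(emb, 2048L)
  # the free-kernel baseline front end learns every tap
  set.seed(1)
  mc <- build_model(default_cnn1d_spec(2, 16000))
  expect_identical(count_params(mc, front_only = TRUE), 80L * 251L + 80L)
})

test_that("chunk posteriors are valid, deterministic, and uniform on silence", {
  set.seed(3)
  m <- build_model(compact_sincnet_spec(4))
  chunk <- stats::rnorm(m$chunk_len)
  chunk <- chunk / max(abs(chunk))
  p1 <- predict_chunk(m, chunk)
  p2 <- predict_chunk(m, chunk)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2)
  p0 <- predict_chunk(m, numeric(m$chunk_len))
  expect_lt(max(abs(p0 - 0.25)), 1e-9)       # symmetric init, zero input
  expect_error(predict_chunk(m, numeric(10)), "chunk length")
  expect_error(predict_chunk(m, rep(NA_real_, m$chunk_len)), "finite")
})

test_that("the softmax head applied to the embedding reproduces the posterior", {
  set.seed(4)
  m <- build_model(compact_sincnet_spec(3))
  chunk <- sin(2 * pi * 700 * seq_len(m$chunk_len) / 16000)
  emb <- extract_embedding(m, chunk)
  head_layer <- m$layers[[length(m$layers)]]
  z <- drop(head_layer$params$w %*% emb + head_layer$params$b)
  expect_equal(drop(exp(z) / sum(exp(z))), unname(predict_chunk(m, chunk)),
               tolerance = 1e-12)
  # distinct posteriors imply distinct embeddings
  chunk2 <- sin(2 * pi * 2500 * seq_len(m$chunk_len) / 16000)
  expect_false(isTRUE(all.equal(extract_embedding(m, chunk2), emb)))
})

test_that("analytic gradients agree with numerical differentiation", {
  model <- fx_mini_model()
  set.seed(7)
  x <- array(stats::rnorm(model$chunk_len * 5), c(model$chunk_len, 1, 5))
  y <- sample(1:3, 5, replace = TRUE)
  lossfn <- function(m) {
    fw <- sincvoice:::model_forward(m, x, training = TRUE)
    sincvoice:::xent_loss(fw$logits, y)$loss
  }
  fw <- sincvoice:::model_forward(model, x, training = TRUE)
  ls <- sincvoice:::xent_loss(fw$logits, y)
  gr <- sincvoice:::model_backward(fw$model, fw$caches, ls$glogits)
  saw_sinc <- FALSE
  for (li in seq_along(model$layers)) {
    if (is.null(gr[[li]])) next
    for (nm in names(gr[[li]])) {
      p <- model$layers[[li]]$params[[nm]]
      for (j in sample(length(p), min(4, length(p)))) {
        h <- 1e-5 * max(1, abs(p[j]))
        m1 <- model; m1$layers[[li]]$params[[nm]][j] <- p[j] + h
        m2 <- model; m2$layers[[li]]$params[[nm]][j] <- p[j] - h
        num <- (lossfn(m1) - lossfn(m2)) / (2 * h)
        ana <- gr[[li]][[nm]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
      }
    }
    if (model$layers[[li]]$type == "sinc_conv") saw_sinc <- TRUE
  }
  expect_true(saw_sinc)   # the band-edge parameters were part of the audit
})

test_that("the 2-D spectrogram baseline runs forward and backward", {
  sp <- network_spec(
    front_end = list(type = "conv2d-spectrogram",
                     stft = list(win_s = 0.01, hop_s = 0.005, n_fft = 256L)),
    conv_layers = list(list(channels = 3L, kernel = c(3L, 3L),
                            stride = c(2L, 2L))),
    pool = c(2L, 2L), fc_layers = 6L, dropout_conv = 0, dropout_fc = 0,
    n_classes = 2L, sample_rate = 16000, chunk_s = 0.05, shift_s = 0.05)
  set.seed(5)
  m <- build_model(sp)
  expect_identical(count_params(m), spec_param_count(sp))
  chunk <- stats::rnorm(m$chunk_len)
  p <- predict_chunk(m, chunk / max(abs(chunk)))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  x <- array(stats::rnorm(m$chunk_len * 3), c(m$chunk_len, 1, 3))
  fw <- sincvoice:::model_forward(m, x, training = TRUE)
  ls <- sincvoice:::xent_loss(fw$logits, c(1L, 2L, 1L))
  gr <- sincvoice:::model_backward(fw$model, fw$caches, ls$glogits)
  gconv <- gr[[which(vapply(m$layers, `[[`, "", "type") == "conv2d")]]
  expect_true(all(is.finite(gconv$w)))
  expect_gt(max(abs(gconv$w)), 0)
})
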