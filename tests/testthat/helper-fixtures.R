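# Shared fixtures, built lazily once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Default 4-class synthetic task: 40 one-second utterances per disorder
# class at 16 kHz, fixed seed.
fx_fourclass <- function() fx_memo("fourclass", function() {
  classes <- c("FD", "Neo", "Pho", "VP")
  waves <- make_waveforms(stats::setNames(rep(40L, 4), classes), seed = 1,
                          overrides = list(duration_s = 1))
  ids <- vapply(waves, `[[`, "", "utterance_id")
  labs <- vapply(waves, `[[`, "", "label")
  plan <- split_dataset(ids, 0.8, seed = 1, labels = labs)
  tv <- ids %in% plan$train_val_ids
  folds <- make_folds(ids[tv], labs[tv], k = 5, seed = 1)
  tr_ids <- names(folds$assignments)[folds$assignments != 1L]
  va_ids <- names(folds$assignments)[folds$assignments == 1L]
  list(classes = classes, waves = waves, ids = ids, labels = labs,
       plan = plan, folds = folds,
       train_cs = build_chunkset_fx(waves[ids %in% tr_ids], classes),
       val_cs = build_chunkset_fx(waves[ids %in% va_ids], classes),
       test_waves = waves[ids %in% plan$test_ids])
})

build_chunkset_fx <- function(waves, classes, chunk_s = 0.2, shift_s = 0.2) {
  sincvoice:::build_chunkset(waves, classes, chunk_s, shift_s)
}

# Small two-class fixture (Normal vs Neo) for cheap training tests.
fx_twoclass <- function() fx_memo("twoclass", function() {
  waves <- make_waveforms(list(Normal = 8L, Neo = 8L), seed = 2,
                          overrides = list(duration_s = 1))
  list(classes = c("Normal", "Neo"), waves = waves,
       cs = build_chunkset_fx(waves, c("Normal", "Neo")))
})

# One SincNet / CNN(1D) pair trained briefly on the four-class task.
fx_trained_pair <- function() fx_memo("trained_pair", function() {
  fx <- fx_fourclass()
  hp <- list(epochs = 5, patience = 99)
  list(
    sinc = fit_model(compact_sincnet_spec(4), fx$train_cs, fx$val_cs, hp, seed = 1),
    cnn = fit_model(compact_cnn1d_spec(4), fx$train_cs, fx$val_cs, hp, seed = 1))
})

# Miniature sinc network with interior band parameters for gradient checks.
fx_mini_model <- function() {
  spec <- network_spec(
    front_end = list(type = "sinc", n_filters = 4L, filter_len = 31L,
                     stride = 2L, window = "hamming",
                     min_low_hz = 50, min_band_hz = 50),
    conv_layers = list(c(3L, 5L, 1L)), pool = 2L, fc_layers = 8L,
    dropout_conv = 0, dropout_fc = 0, n_classes = 3L, sample_rate = 16000,
    chunk_s = 0.02, shift_s = 0.01)
  set.seed(42)
  model <- build_model(spec)
  model$layers[[1]]$params$raw_low <- c(120, 340, 800, 1500)
  model$layers[[1]]$params$raw_band <- c(200, 420, 900, 1300)
  model
}

# Filterbank with exactly the requested bands (assumes f1 >= 50, width >= 50).
read_filterbank_from_bands <- function(tab, fs, filter_len = 251,
                                       window = "hamming") {
  structure(list(n_filters = nrow(tab), filter_len = as.integer(filter_len),
                 sample_rate = fs, window = window,
                 min_low_hz = 50, min_band_hz = 50,
                 raw_low = tab$f1 - 50, raw_band = tab$f2 - tab$f1 - 50),
            class = "sinc_filterbank")
}

# DFT magnitude of a kernel at arbitrary normalized frequencies
# (chunked dense DFT so long kernels stay cheap).
kernel_dft_mag <- function(g, f_norm) {
  n <- seq.int(-(length(g) - 1) / 2, (length(g) - 1) / 2)
  out <- numeric(length(f_norm))
  for (s in seq(1, length(f_norm), by = 256)) {
    idx <- s:min(s + 255, length(f_norm))
    out[idx] <- Mod(exp(-2i * pi * outer(f_norm[idx], n)) %*% g)
  }
  out
}

# High-band (>= 2.5 kHz) energy fraction and frame-RMS coefficient of
# variation: the two summary features used to probe class signatures.
high_band_ratio <- function(w) {
  ps <- welch_psd(w$samples, w$sample_rate, n = 512)
  half <- seq_len(257)
  f <- attr(ps, "frequencies")[half]
  sum(ps[half][f >= 2500]) / sum(ps[half])
}

frame_rms_cv <- function(w, frame_s = 0.05) {
  fl <- round(frame_s * w$sample_rate)
  n <- fl * (length(w$samples) %/% fl)
  r <- sqrt(colMeans(matrix(w$samples[seq_len(n)], fl)^2))
  stats::sd(r) / mean(r)
}
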