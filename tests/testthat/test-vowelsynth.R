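test_that("unperturbed glottal source is exactly periodic", {
  p <- synth_params(jitter_pct = 0, shimmer_pct = 0, duration_s = 1)
  src <- glottal_source(p, 4)
  on <- which(src[-1] > 1e-9 & utils::head(src, -1) <= 1e-9)
  expect_true(all(diff(on) == round(16000 / 140)))
})

test_that("measured cycle jitter matches the requested percentage", {
  p <- synth_params(jitter_pct = 2, shimmer_pct = 0, duration_s = 3)
  src <- glottal_source(p, 11)
  on <- which(src[-1] > 1e-9 & utils::head(src, -1) <= 1e-9)
  cyc <- diff(on)
  expect_gte(length(cyc), 200)
  expect_equal(stats::sd(cyc) / mean(cyc), 0.02, tolerance = 0.005 / 0.02)
})

test_that("the glottal source is deterministic given the seed", {
  p <- synth_params(jitter_pct = 1.5, shimmer_pct = 4, duration_s = 0.5)
  expect_identical(glottal_source(p, 21), glottal_source(p, 21))
  expect_false(identical(glottal_source(p, 21), glottal_source(p, 22)))
})

test_that("formant filter places resonances at the requested centers", {
  set.seed(3)
  wn <- stats::rnorm(48000)
  v <- formant_filter(wn, list(c(800, 80), c(1200, 90), c(2800, 120)), 16000)
  ps <- welch_psd(v, 16000, n = 1024)
  half <- seq_len(513)
  f <- attr(ps, "frequencies")[half]
  pw <- ps[half]
  for (center in c(800, 1200, 2800)) {
    win <- which(abs(f - center) <= 200)
    loc <- win[which.max(pw[win])]
    expect_true(loc > min(win) && loc < max(win))   # a true local maximum
    expect_lt(abs(f[loc] - center), 50)
  }
})

test_that("a single resonator has the requested -3 dB bandwidth", {
  h <- formant_filter(c(1, numeric(16383)), list(c(800, 80)), 16000)
  H <- Mod(stats::fft(h))[1:8193]
  f <- (0:8192) * 16000 / 16384
  width <- diff(range(f[H > max(H) / sqrt(2)]))
  expect_equal(width, 80, tolerance = 0.25)
})

test_that("formant filter is linear and validates its configuration", {
  expect_true(all(formant_filter(numeric(100), list(c(800, 80))) == 0))
  expect_error(formant_filter(stats::rnorm(10), list(c(800, 0))), "positive")
  expect_error(formant_filter(stats::rnorm(10), list(c(9000, 80)), 16000),
               "Nyquist")
})

test_that("class presets produce the documented spectral signatures", {
  neo <- synth_vowel("Neo", seed = 9)
  nor <- synth_vowel("Normal", seed = 9)
  expect_gt(high_band_ratio(neo) / high_band_ratio(nor), 3)
  vp <- synth_vowel("VP", seed = 9)
  fd <- synth_vowel("FD", seed = 9)
  expect_gt(frame_rms_cv(vp) / frame_rms_cv(fd), 2)
  pho <- synth_vowel("Pho", seed = 9)     # intermediate high-band level
  expect_gt(high_band_ratio(pho), high_band_ratio(nor))
  expect_lt(high_band_ratio(pho), high_band_ratio(neo))
})

test_that("vowels are duration-exact, clip-free and deterministic", {
  w <- synth_vowel("Normal", seed = 12)
  expect_length(w$samples, 48000L)         # 3 s at 16 kHz
  expect_lte(max(abs(w$samples)), 0.9 + 1e-12)
  w2 <- synth_vowel("Normal", seed = 12)
  expect_identical(w$samples, w2$samples)
  expect_error(synth_vowel("Polyp"), "unknown label")
})

test_that("summary features linearly separate noisy from modulated classes", {
  labs <- c("Normal", "FD", "Neo", "VP")
  waves <- make_waveforms(stats::setNames(rep(50L, 4), labs), seed = 31,
                          overrides = list(duration_s = 1))
  feats <- t(vapply(waves, function(w) c(high_band_ratio(w), frame_rms_cv(w)),
                    numeric(2)))
  y <- vapply(waves, `[[`, "", "label") %in% c("Neo", "VP")
  fit <- suppressWarnings(stats::glm(y ~ feats[, 1] + feats[, 2],
                                     family = stats::binomial))
  expect_gte(mean((fit$fitted.values > 0.5) == y), 0.95)
})

test_that("datasets are written with an exact manifest", {
  out <- withr::local_tempdir()
  man <- make_dataset(list(Neo = 5, Pho = 5, VP = 5, Normal = 5), seed = 1,
                      out_dir = out, overrides = list(duration_s = 0.3))
  expect_identical(nrow(man), 20L)
  expect_identical(names(man), c("utterance_id", "path", "label"))
  expect_true(all(table(man$label) == 5L))
  expect_setequal(unique(man$label), c("Neo", "Pho", "VP", "Normal"))
  expect_true(all(file.exists(man$path)))
  empty <- make_dataset(list(), seed = 1, out_dir = file.path(out, "e"))
  expect_identical(nrow(empty), 0L)
  expect_identical(readLines(attr(empty, "path")), "utterance_id,path,label")
})

test_that("WAV files round-trip and are byte-identical across rebuilds", {
  w <- synth_vowel("FD", seed = 77, overrides = list(duration_s = 0.4))
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(w$samples, w$sample_rate, p1)
  write_wav(synth_vowel("FD", seed = 77,
                        overrides = list(duration_s = 0.4))$samples,
            w$sample_rate, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  rd <- read_wav(p1)
  expect_identical(rd$sample_rate, 16000L)
  expect_lt(max(abs(rd$samples - w$samples)), 1 / 32767)
})

test_that("loading a manifest recovers labeled waveforms", {
  out <- withr::local_tempdir()
  man <- make_dataset(list(Normal = 2, VP = 2), seed = 3, out_dir = out,
                      overrides = list(duration_s = 0.3))
  waves <- load_manifest(man)
  expect_length(waves, 4L)
  expect_identical(vapply(waves, `[[`, "", "label"), man$label)
  expect_identical(vapply(waves, `[[`, "", "utterance_id"), man$utterance_id)
})
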