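test_that("kernel center tap equals twice the normalized bandwidth", {
  g <- make_sinc_kernel(0.05 * 16000, 0.10 * 16000, 251, 16000, "none")
  expect_equal(g[126], 0.10)
  gw <- make_sinc_kernel(0.05 * 16000, 0.10 * 16000, 251, 16000, "hamming")
  expect_equal(gw[126], 0.10)  # Hamming taper is 1 at the center tap
})

test_that("invalid band or tap count is rejected", {
  expect_error(make_sinc_kernel(1600, 1600, 251, 16000), "empty band")
  expect_error(make_sinc_kernel(2000, 1000, 251, 16000), "empty band")
  expect_error(make_sinc_kernel(100, 9000, 251, 16000), "Nyquist")
  expect_error(make_sinc_kernel(100, 500, 250, 16000), "odd")
  expect_error(make_sinc_kernel(-5, 500, 251, 16000), "nonnegative")
})

test_that("kernels are even-symmetric before and after windowing", {
  for (band in list(c(100, 400), c(800, 1600), c(3000, 7900))) {
    for (win in c("none", "hamming")) {
      g <- make_sinc_kernel(band[1], band[2], 251, 16000, win)
      expect_lt(max(abs(g - rev(g))), 1e-9)
    }
  }
})

test_that("band-pass kernel is the difference of two low-pass kernels", {
  g <- make_sinc_kernel(800, 1600, 251, 16000, "none")
  d <- make_sinc_kernel(0, 1600, 251, 16000, "none") -
    make_sinc_kernel(0, 800, 251, 16000, "none")
  expect_lt(max(abs(g - d)), 1e-9)
})

test_that("long unwindowed kernel matches the ideal band-pass response", {
  g <- make_sinc_kernel(0.05 * 16000, 0.10 * 16000, 4001, 16000, "none")
  expect_equal(kernel_dft_mag(g, 0.075), 1.0, tolerance = 0.02)
  expect_lt(kernel_dft_mag(g, 0.20), 0.02)
})

test_that("constraint mapping reproduces the documented examples", {
  expect_equal(constrain_cutoffs(0, 0, 50, 50, 16000), list(f1 = 50, f2 = 100))
  expect_equal(constrain_cutoffs(-200, 300, 50, 50, 16000),
               list(f1 = 250, f2 = 600))
  expect_equal(constrain_cutoffs(5000, 1e7, 50, 50, 16000)$f2, 8000)
})

test_that("constraint mapping is total over random parameter pairs", {
  set.seed(99)
  rl <- stats::runif(1e6, -1e6, 1e6)
  rb <- stats::runif(1e6, -1e6, 1e6)
  ct <- constrain_cutoffs(rl, rb, 50, 50, 16000)
  expect_true(all(ct$f1 > 0))
  expect_true(all(ct$f1 < ct$f2))
  expect_true(all(ct$f2 <= 8000))
})

test_that("filterbank initialization tiles the spectrum as requested", {
  fb <- init_filterbank(80, 16000)
  expect_equal(length(fb$raw_low) + length(fb$raw_band), 160L)
  ct <- cutoffs(fb)
  expect_true(all(diff(ct$f1_hz) > 0))
  centers <- (ct$f1_hz + ct$f2_hz) / 2
  expect_gt(sum(centers < 1000),             # mel: denser low than high
            sum(centers >= 6000) / 2)
  fb1 <- init_filterbank(1, 16000, "linear")
  ct1 <- cutoffs(fb1)
  expect_equal(ct1$f1_hz, 50)
  expect_equal(ct1$f2_hz, 8000)
  expect_error(init_filterbank(4, 16000, "log"))
  expect_identical(cutoffs(init_filterbank(12, 16000)),
                   cutoffs(init_filterbank(12, 16000)))  # deterministic
})

test_that("filterbank application is linear and recovers kernels", {
  fb <- init_filterbank(6, 16000, filter_len = 101)
  expect_true(all(apply_filterbank(numeric(500), fb) == 0))
  imp <- numeric(201); imp[101] <- 1
  y <- apply_filterbank(imp, fb)
  k <- kernel_matrix(fb)
  expect_equal(y, k[, rev(seq_len(101))], tolerance = 1e-12,
               ignore_attr = TRUE)              # reversed = itself by symmetry
  expect_error(apply_filterbank(numeric(50), fb), "shorter")
})

test_that("a tone passes the matched band and is rejected elsewhere", {
  fs <- 16000
  tone <- sin(2 * pi * 440 * seq_len(fs) / fs)
  bank_match <- read_filterbank_from_bands(data.frame(f1 = 300, f2 = 600), fs)
  bank_off <- read_filterbank_from_bands(data.frame(f1 = 3000, f2 = 4000), fs)
  r1 <- sqrt(mean(apply_filterbank(tone, bank_match)^2))
  r2 <- sqrt(mean(apply_filterbank(tone, bank_off)^2))
  expect_gt(r1 / r2, 20)
})

test_that("magnitude response peaks inside each channel's band", {
  fb <- init_filterbank(16, 16000, filter_len = 251)
  resp <- filterbank_response(fb, 4096)
  f <- attr(resp, "frequencies")
  ct <- cutoffs(fb)
  bin <- 16000 / 4096
  for (i in seq_len(16)) {
    pk <- f[which.max(resp[i, ])]
    expect_gte(pk, ct$f1_hz[i] - bin)
    expect_lte(pk, ct$f2_hz[i] + bin)
  }
  expect_error(filterbank_response(fb, 128), "at least")
})

test_that("disjoint bands have low cross-band leakage", {
  fs <- 16000
  bank <- read_filterbank_from_bands(
    data.frame(f1 = c(500, 5000), f2 = c(1500, 6500)), fs)
  resp <- filterbank_response(bank, 4096)
  f <- attr(resp, "frequencies")
  in1 <- f >= 500 & f <= 1500
  in2 <- f >= 5000 & f <= 6500
  expect_lt(max(resp[1, in2]), 0.1 * max(resp[1, in1]))
  expect_lt(max(resp[2, in1]), 0.1 * max(resp[2, in2]))
})

test_that("band tables round-trip through CSV", {
  fb <- init_filterbank(20, 16000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_filterbank(fb, path)
  expect_identical(readLines(path, n = 1), "channel,f1_hz,f2_hz")
  fb2 <- read_filterbank(path, 16000)
  expect_equal(cutoffs(fb2)$f1_hz, cutoffs(fb)$f1_hz, tolerance = 1e-5)
  expect_equal(cutoffs(fb2)$f2_hz, cutoffs(fb)$f2_hz, tolerance = 1e-5)
})
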