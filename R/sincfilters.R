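#' @useDynLib sincvoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Window taper for sinc kernels
#'
#' Returns the taper applied pointwise to each band-pass kernel. A truncated
#' ideal sinc kernel has large spectral ripple; a Hamming taper confines each
#' channel's response to its band at the cost of a slightly wider transition.
#'
#' @param filter_len Odd tap count.
#' @param window `"hamming"` or `"none"`.
#' @return Numeric vector of length `filter_len`.
#' @keywords internal
sinc_window <- function(filter_len, window = c("hamming", "none")) {
  window <- match.arg(window)
  if (window == "none") return(rep(1, filter_len))
  n <- seq_len(filter_len) - 1L
  0.54 - 0.46 * cos(2 * pi * n / (filter_len - 1))
}

#' Band-pass sinc kernel
#'
#' Builds the impulse response of an ideal band-pass filter as the difference
#' of two scaled sinc low-pass kernels,
#' `g[n] = 2 f2 sinc(2 pi f2 n) - 2 f1 sinc(2 pi f1 n)`, with frequencies
#' normalized by the sample rate, `sinc(x) = sin(x)/x` and `sinc(0) = 1`,
#' evaluated at integer offsets `n` in `[-(L-1)/2, (L-1)/2]`, then multiplied
#' by the window taper. The result is even-symmetric about the center tap.
#'
#' @param f1,f2 Lower and upper cutoff frequencies in Hz, `0 <= f1 < f2 <=
#'   sample_rate/2`.
#' @param filter_len Odd tap count `L`.
#' @param sample_rate Sample rate in Hz.
#' @param window Taper id, see [sinc_window()].
#' @return Numeric vector of length `filter_len`.
#' @examples
#' g <- make_sinc_kernel(300, 600, 251, 16000)
#' g[126] == 2 * (600 - 300) / 16000 * sinc_window(251)[126]
#' @export
make_sinc_kernel <- function(f1, f2, filter_len, sample_rate,
                             window = c("hamming", "none")) {
  if (filter_len %% 2 == 0) stop("filter_len must be odd")
  if (f1 < 0) stop("f1 must be nonnegative")
  if (f1 >= f2) stop("empty band: f1 must be strictly below f2")
  if (f2 > sample_rate / 2) stop("f2 exceeds the Nyquist frequency")
  w <- sinc_window(filter_len, window)
  n <- seq.int(-(filter_len - 1) / 2, (filter_len - 1) / 2)
  lp <- function(fn) ifelse(n == 0, 2 * fn, sin(2 * pi * fn * n) / (pi * n))
  (lp(f2 / sample_rate) - lp(f1 / sample_rate)) * w
}

#' Map unconstrained parameters to valid cutoff frequencies
#'
#' The learnable per-channel scalars are unconstrained reals; this
#' reparameterization guarantees `min_low_hz <= f1 < f2 <= Nyquist` for any
#' values reached during optimization:
#' `f1 = min(min_low_hz + |raw_low|, Nyquist - min_band_hz)`,
#' `f2 = min(f1 + min_band_hz + |raw_band|, Nyquist)`. It is total and
#' piecewise smooth, so gradient steps can never produce an invalid band.
#'
#' @param raw_low,raw_band Unconstrained reals (vectorized).
#' @param min_low_hz,min_band_hz Positive floors in Hz (defaults 50), keeping
#'   bands above DC and wider than typical fundamental-frequency resolution.
#' @param sample_rate Sample rate in Hz.
#' @return List with numeric vectors `f1` and `f2` in Hz.
#' @export
constrain_cutoffs <- function(raw_low, raw_band, min_low_hz = 50,
                              min_band_hz = 50, sample_rate = 16000) {
  f1 <- pmin(min_low_hz + abs(raw_low), sample_rate / 2 - min_band_hz)
  f2 <- pmin(f1 + min_band_hz + abs(raw_band), sample_rate / 2)
  list(f1 = f1, f2 = f2)
}

#' Initialize a learnable sinc filterbank
#'
#' Tiles `[min_low_hz, Nyquist]` with `n_filters` contiguous band edges on a
#' mel or linear scale and stores the unconstrained parameters that reproduce
#' those edges through [constrain_cutoffs()]. The bank carries exactly
#' `2 * n_filters` learnable scalars (one low-cutoff and one bandwidth
#' parameter per channel). Mel spacing places more, narrower bands at low
#' frequency where vowel structure (fundamental and first formants) lives.
#'
#' @param n_filters Number of band-pass channels.
#' @param sample_rate Sample rate in Hz.
#' @param scheme Edge spacing, `"mel"` or `"linear"`.
#' @param filter_len Odd tap count per kernel.
#' @param window Taper id.
#' @param min_low_hz,min_band_hz Constraint floors in Hz.
#' @return An object of class `sinc_filterbank`.
#' @examples
#' fb <- init_filterbank(80, 16000)
#' length(fb$raw_low) + length(fb$raw_band)  # 160 learnable scalars
#' @export
init_filterbank <- function(n_filters, sample_rate, scheme = c("mel", "linear"),
                            filter_len = 251, window = "hamming",
                            min_low_hz = 50, min_band_hz = 50) {
  scheme <- match.arg(scheme)
  if (n_filters < 1) stop("n_filters must be at least 1")
  nyq <- sample_rate / 2
  edges <- switch(scheme,
    mel = mel_to_hz(seq(hz_to_mel(min_low_hz), hz_to_mel(nyq), length.out = n_filters + 1)),
    linear = seq(min_low_hz, nyq, length.out = n_filters + 1))
  f1 <- edges[seq_len(n_filters)]
  f2 <- pmin(pmax(edges[-1], f1 + min_band_hz), nyq)
  bank <- structure(list(
    n_filters = as.integer(n_filters), filter_len = as.integer(filter_len),
    sample_rate = sample_rate, window = window,
    min_low_hz = min_low_hz, min_band_hz = min_band_hz,
    raw_low = f1 - min_low_hz,
    raw_band = pmax(f2 - f1 - min_band_hz, 0)),
    class = "sinc_filterbank")
  bank
}

#' Current cutoff frequencies of a filterbank
#'
#' @param bank A `sinc_filterbank`.
#' @return Data frame with columns `channel`, `f1_hz`, `f2_hz`.
#' @export
cutoffs <- function(bank) {
  ct <- constrain_cutoffs(bank$raw_low, bank$raw_band, bank$min_low_hz,
                          bank$min_band_hz, bank$sample_rate)
  data.frame(channel = seq_len(bank$n_filters), f1_hz = ct$f1, f2_hz = ct$f2)
}

#' Kernel matrix of a filterbank
#'
#' @param bank A `sinc_filterbank`.
#' @param window Override the bank's taper (e.g. `"none"` for analysis).
#' @return `n_filters x filter_len` matrix; row i is channel i's kernel.
#' @export
kernel_matrix <- function(bank, window = bank$window) {
  ct <- cutoffs(bank)
  t(vapply(seq_len(bank$n_filters), function(i)
    make_sinc_kernel(ct$f1_hz[i], ct$f2_hz[i], bank$filter_len,
                     bank$sample_rate, window),
    numeric(bank$filter_len)))
}

#' Filter a waveform chunk through every channel
#'
#' Valid (unpadded) linear convolution of the chunk with each channel's
#' kernel; row i of the result is channel i's output.
#'
#' @param chunk Numeric vector, length at least `filter_len`.
#' @param bank A `sinc_filterbank`.
#' @return `n_filters x (length(chunk) - filter_len + 1)` matrix.
#' @export
apply_filterbank <- function(chunk, bank) {
  if (length(chunk) < bank$filter_len)
    stop("chunk shorter than filter_len")
  k <- kernel_matrix(bank)
  w <- k[, rev(seq_len(ncol(k))), drop = FALSE]  # flip: convolution, not correlation
  x <- array(chunk, dim = c(length(chunk), 1L, 1L))
  y <- conv1d_fwd(x, w, 1L)      # (Tout, n_filters, 1)
  t(matrix(y, nrow = dim(y)[1]))
}

#' One-sided magnitude responses of a filterbank
#'
#' DFT magnitude of each (windowed) kernel, zero-padded to `n_fft`. The peak
#' of each channel lies inside its `[f1, f2]` band to within one bin.
#'
#' @param bank A `sinc_filterbank`.
#' @param n_fft DFT length, at least `filter_len`.
#' @return `n_filters x (n_fft/2 + 1)` matrix with attribute `frequencies`
#'   (Hz per column).
#' @export
filterbank_response <- function(bank, n_fft = 2048) {
  if (n_fft < bank$filter_len) stop("n_fft must be at least filter_len")
  k <- kernel_matrix(bank)
  nb <- n_fft %/% 2 + 1L
  resp <- t(apply(k, 1, function(g)
    Mod(stats::fft(c(g, rep(0, n_fft - length(g)))))[seq_len(nb)]))
  attr(resp, "frequencies") <- (seq_len(nb) - 1) * bank$sample_rate / n_fft
  resp
}

#' Export learned bands as a plain-text table
#'
#' Writes `channel,f1_hz,f2_hz` (CSV, header row, 6-decimal fixed point) so
#' learned bands are inspectable and diffable.
#'
#' @param bank A `sinc_filterbank`.
#' @param path Output file path.
#' @export
write_filterbank <- function(bank, path) {
  ct <- cutoffs(bank)
  lines <- c("channel,f1_hz,f2_hz",
             sprintf("%d,%.6f,%.6f", ct$channel, ct$f1_hz, ct$f2_hz))
  writeLines(lines, path)
  invisible(path)
}

#' Read a filterbank band table
#'
#' Reconstructs a `sinc_filterbank` whose constrained cutoffs reproduce the
#' stored `f1_hz`/`f2_hz` columns (bands narrower than `min_band_hz` are
#' widened to the floor, as no parameter setting can express them).
#'
#' @param path CSV written by [write_filterbank()].
#' @param sample_rate,filter_len,window,min_low_hz,min_band_hz Bank settings
#'   not stored in the table.
#' @return A `sinc_filterbank`.
#' @export
read_filterbank <- function(path, sample_rate, filter_len = 251,
                            window = "hamming", min_low_hz = 50,
                            min_band_hz = 50) {
  tab <- utils::read.csv(path)
  structure(list(
    n_filters = nrow(tab), filter_len = as.integer(filter_len),
    sample_rate = sample_rate, window = window,
    min_low_hz = min_low_hz, min_band_hz = min_band_hz,
    raw_low = pmax(tab$f1_hz - min_low_hz, 0),
    raw_band = pmax(tab$f2_hz - tab$f1_hz - min_band_hz, 0)),
    class = "sinc_filterbank")
}

#' @export
print.sinc_filterbank <- function(x, ...) {
  ct <- cutoffs(x)
  cat(sprintf("sinc filterbank: %d channels, %d taps, %g Hz, %s window\n",
              x$n_filters, x$filter_len, x$sample_rate, x$window))
  cat(sprintf("bands: %.0f-%.0f Hz ... %.0f-%.0f Hz (%d learnable scalars)\n",
              ct$f1_hz[1], ct$f2_hz[1], ct$f1_hz[x$n_filters],
              ct$f2_hz[x$n_filters], 2L * x$n_filters))
  invisible(x)
}
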