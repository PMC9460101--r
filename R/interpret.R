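# Filter-level interpretability: per-channel time/frequency portraits of
# the learned front end and averaged Welch power spectral densities of
# filterbank-processed voices.

#' Welch power spectral density
#'
#' Mean modified periodogram over Hamming-tapered segments with 50% overlap,
#' density-scaled so that `sum(psd) * fs / n` approximates the mean signal
#' power. All `n` two-sided bins are retained.
#'
#' @param x Numeric signal.
#' @param fs Sample rate in Hz.
#' @param n Segment length = number of bins (default 256).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Numeric vector of `n` power values with attribute `frequencies`
#'   (two-sided bin centers in Hz).
#' @export
welch_psd <- function(x, fs, n = 256, overlap = 0.5) {
  if (length(x) < n) stop("signal shorter than one PSD segment")
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq.int(1L, length(x) - n + 1L, by = hop)
  segs <- matrix(x[outer(seq_len(n) - 1L, starts, "+")], nrow = n) * w
  psd <- rowMeans(Mod(stats::mvfft(segs))^2) / (fs * sum(w^2))
  attr(psd, "frequencies") <- (seq_len(n) - 1) * fs / n
  psd
}

front_end_kernels <- function(front_end) {
  if (inherits(front_end, "sinc_filterbank"))
    return(list(k = kernel_matrix(front_end), bank = front_end))
  if (inherits(front_end, "voice_model")) {
    l1 <- front_end$layers[[1]]
    if (l1$type == "sinc_conv") {
      kk <- sinc_layer_kernels(l1)
      return(list(k = kk$k, f1 = kk$f1, f2 = kk$f2,
                  fs = l1$sample_rate, bank = sinc_layer_bank(l1)))
    }
    if (l1$type == "conv1d")
      return(list(k = l1$params$w, fs = front_end$spec$sample_rate))
    stop("model front end is not a 1-D filter layer")
  }
  stop("front_end must be a sinc_filterbank or a voice_model")
}

#' Time/frequency portrait of one front-end channel
#'
#' Returns the learned kernel of the requested channel together with its
#' one-sided DFT magnitude. For a sinc front end the response is band-pass
#' with a single dominant band delimited by the learned cutoffs; a free
#' first-layer convolution carries no such constraint.
#'
#' @param model A `voice_model` or `sinc_filterbank`.
#' @param channel_index Channel to portray (1-based).
#' @param n_fft DFT length for the response.
#' @return List with `taps`, `response`, `frequencies`, and for sinc front
#'   ends the band edges `f1`, `f2`.
#' @export
channel_portrait <- function(model, channel_index, n_fft = 2048) {
  fk <- front_end_kernels(model)
  if (channel_index < 1 || channel_index > nrow(fk$k))
    stop("channel_index out of range")
  taps <- fk$k[channel_index, ]
  fs <- if (!is.null(fk$fs)) fk$fs else fk$bank$sample_rate
  nb <- n_fft %/% 2 + 1L
  resp <- Mod(stats::fft(c(taps, rep(0, n_fft - length(taps)))))[seq_len(nb)]
  out <- list(taps = taps, response = resp,
              frequencies = (seq_len(nb) - 1) * fs / n_fft)
  if (!is.null(fk$bank)) {
    ct <- cutoffs(fk$bank)
    out$f1 <- ct$f1_hz[channel_index]
    out$f2 <- ct$f2_hz[channel_index]
  }
  out
}

#' Averaged power spectral density of front-end outputs
#'
#' Passes the full waveform through every channel of the front end (valid
#' convolution), computes an `n_psd`-bin Welch PSD per channel (giving an
#' `n_channels x n_psd` matrix), and averages across channels into a single
#' profile.
#'
#' @param waveform A `labeled_waveform` or numeric vector.
#' @param front_end A `sinc_filterbank` or `voice_model` (its first layer is
#'   used).
#' @param n_psd PSD bin count (default 256).
#' @param sample_rate Required when `waveform` is a bare numeric vector.
#' @return A `psd_profile`: list with `bins` (length `n_psd`),
#'   `bin_frequencies` (Hz) and `source`.
#' @export
psd_profile <- function(waveform, front_end, n_psd = 256, sample_rate = NULL) {
  if (inherits(waveform, "labeled_waveform")) {
    x <- waveform$samples
    fs <- waveform$sample_rate
    src <- waveform$utterance_id
  } else {
    x <- as.numeric(waveform)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate is required for a bare numeric waveform")
    src <- "waveform"
  }
  fk <- front_end_kernels(front_end)
  if (length(x) < ncol(fk$k) + n_psd)
    stop("waveform too short for filtering plus one PSD segment")
  feat <- conv1d_fwd(array(x, c(length(x), 1L, 1L)),
                     fk$k[, rev(seq_len(ncol(fk$k))), drop = FALSE], 1L)
  feat <- matrix(feat, nrow = dim(feat)[1])      # time x channels
  mat <- apply(feat, 2, welch_psd, fs = fs, n = n_psd)  # n_psd x channels
  structure(list(bins = rowMeans(mat),
                 bin_frequencies = (seq_len(n_psd) - 1) * fs / n_psd,
                 source = src, n_channels = ncol(mat)),
            class = "psd_profile")
}

profile_peak_hz <- function(p) {
  half <- seq_len(length(p$bins) %/% 2 + 1L)     # one-sided half for peaks
  p$bin_frequencies[half][which.max(p$bins[half])]
}

band_energy <- function(p, band) {
  half <- seq_len(length(p$bins) %/% 2 + 1L)
  f <- p$bin_frequencies[half]
  sum(p$bins[half][f >= band[1] & f <= band[2]])
}

#' Coverage of a frequency band by a filterbank
#'
#' Fraction of `[band[1], band[2]]` covered by the union of the bank's (or
#' sinc-front-end model's) `[f1, f2]` channel intervals; used to check that
#' training kept/placed band-pass channels over a discriminative band.
#'
#' @param model A `sinc_filterbank` or a `voice_model` with a sinc front end.
#' @param band `c(lo_hz, hi_hz)`.
#' @param resolution_hz Grid step for the coverage measure.
#' @return Covered fraction in `[0, 1]`.
#' @export
band_coverage <- function(model, band, resolution_hz = 5) {
  fk <- front_end_kernels(model)
  if (is.null(fk$bank)) stop("band coverage requires a sinc front end")
  ct <- cutoffs(fk$bank)
  grid <- seq(band[1], band[2], by = resolution_hz)
  covered <- vapply(grid, function(f) any(f >= ct$f1_hz & f <= ct$f2_hz), TRUE)
  mean(covered)
}

#' Compare two averaged PSD profiles
#'
#' Reports per-profile peak frequency, their separation, energy within the
#' requested bands (absolute and as a fraction of each profile's total) and
#' the a/b ratio of those fractions, optionally writing an overlay plot.
#' Fractions are compared rather than raw energies because the two front
#' ends have incommensurate gains (unit-gain band-pass kernels versus free
#' kernels of arbitrary scale).
#'
#' @param profile_a,profile_b `psd_profile`s on identical bin grids.
#' @param bands Named list of `c(lo_hz, hi_hz)` bands (default: a first
#'   formant band, 600-1000 Hz).
#' @param file Optional PNG path for the overlay figure.
#' @return List with `peak_hz` (a, b), `peak_separation_hz`,
#'   `band_energy` and `band_fraction` (per band, per profile) and
#'   `band_ratio` (fraction a / fraction b).
#' @export
compare_profiles <- function(profile_a, profile_b,
                             bands = list(first_formant = c(600, 1000)),
                             file = NULL) {
  if (!isTRUE(all.equal(profile_a$bin_frequencies, profile_b$bin_frequencies)))
    stop("profiles are on different bin grids")
  full <- range(profile_a$bin_frequencies)
  be <- lapply(bands, function(bd)
    c(a = band_energy(profile_a, bd), b = band_energy(profile_b, bd)))
  bf <- lapply(bands, function(bd)
    c(a = band_energy(profile_a, bd) / band_energy(profile_a, full),
      b = band_energy(profile_b, bd) / band_energy(profile_b, full)))
  out <- list(peak_hz = c(a = profile_peak_hz(profile_a),
                          b = profile_peak_hz(profile_b)),
              peak_separation_hz = abs(profile_peak_hz(profile_a) -
                                       profile_peak_hz(profile_b)),
              band_energy = be, band_fraction = bf,
              band_ratio = vapply(bf, function(e) e[["a"]] / e[["b"]], 0))
  if (!is.null(file)) {
    half <- seq_len(length(profile_a$bins) %/% 2 + 1L)
    f <- profile_a$bin_frequencies[half]
    grDevices::png(file, width = 700, height = 500)
    graphics::matplot(f, cbind(10 * log10(profile_a$bins[half] + 1e-20),
                               10 * log10(profile_b$bins[half] + 1e-20)),
                      type = "l", lty = 1, col = c("black", "red"),
                      xlab = "frequency (Hz)", ylab = "PSD (dB/Hz)",
                      main = "averaged front-end PSD")
    graphics::legend("topright", legend = c(profile_a$source, profile_b$source),
                     col = c("black", "red"), lty = 1)
    grDevices::dev.off()
  }
  out
}

#' Overlay training/validation loss curves of several runs
#'
#' Convergence comparison between models (e.g. the sinc network against the
#' free-kernel baseline): one curve per training state.
#'
#' @param states Named list of training `state` lists from [fit_model()].
#' @param file Optional PNG path.
#' @param which `"val"` (default) or `"train"` losses.
#' @return Invisibly, the matrix of plotted losses (epochs x runs).
#' @export
plot_loss_curves <- function(states, file = NULL, which = c("val", "train")) {
  which <- match.arg(which)
  series <- lapply(states, function(s)
    if (which == "val") s$val_losses else s$epoch_losses)
  n <- max(lengths(series))
  m <- vapply(series, function(x) c(x, rep(NA, n - length(x))), numeric(n))
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::matplot(seq_len(n), m, type = "l", lty = 1, lwd = 2,
                    col = seq_along(states), xlab = "epoch",
                    ylab = paste(which, "loss"), main = "training efficiency")
  graphics::legend("topright", legend = names(states),
                   col = seq_along(states), lty = 1, lwd = 2)
  invisible(m)
}

#' @export
print.psd_profile <- function(x, ...) {
  cat(sprintf("PSD profile (%s): %d bins, %d channels, peak %.0f Hz\n",
              x$source, length(x$bins), x$n_channels, profile_peak_hz(x)))
  invisible(x)
}
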