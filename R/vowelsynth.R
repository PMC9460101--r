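# Source-filter synthesis of sustained /a/ vowels with controllable
# dysphonia cues: cycle-to-cycle period perturbation (jitter), cycle
# amplitude perturbation (shimmer), additive high-frequency noise, and slow
# amplitude modulation of the energy trajectory.

#' Voice class labels
#'
#' Normal voice plus the four disorder categories: functional dysphonia
#' (FD, stationary envelope), neoplasm (Neo, strong high-frequency
#' components), phonotrauma (Pho, intermediate high-frequency interference)
#' and vocal palsy (VP, nonstationary energy trajectory).
#' @export
voice_classes <- function() c("Normal", "FD", "Neo", "Pho", "VP")

#' Synthesis parameters
#'
#' @param f0_hz Base fundamental frequency.
#' @param jitter_pct Cycle-to-cycle period perturbation as a percentage of
#'   the period.
#' @param shimmer_pct Cycle-to-cycle amplitude perturbation in percent.
#' @param formants List of `c(center_hz, bandwidth_hz)` resonances; the
#'   default triple (800, 1200, 2800 Hz) is a canonical /a/ configuration.
#' @param hf_noise_db Level of high-frequency noise relative to the voiced
#'   signal RMS, in dB.
#' @param hf_noise_band `c(lo_hz, hi_hz)` band of the added noise; the
#'   default puts it above 2.5 kHz (upper edge at Nyquist means high-pass).
#' @param am_depth Slow amplitude-modulation depth in `[0, 1]`.
#' @param am_rate_hz Modulation rate in Hz.
#' @param duration_s Utterance duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(f0_hz = 140, jitter_pct = 0.4, shimmer_pct = 2,
                         formants = list(c(800, 80), c(1200, 90), c(2800, 120)),
                         hf_noise_db = -45, hf_noise_band = c(2500, NA),
                         am_depth = 0, am_rate_hz = 2.5,
                         duration_s = 3, sample_rate = 16000) {
  if (is.na(hf_noise_band[2])) hf_noise_band[2] <- sample_rate / 2
  if (f0_hz <= 0) stop("f0_hz must be positive")
  if (jitter_pct < 0 || shimmer_pct < 0) stop("percentages must be nonnegative")
  if (am_depth < 0 || am_depth > 1) stop("am_depth must lie in [0, 1]")
  if (any(vapply(formants, `[`, 0, 1) >= sample_rate / 2))
    stop("formant centers must lie below the Nyquist frequency")
  structure(list(f0_hz = f0_hz, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, formants = formants,
                 hf_noise_db = hf_noise_db, hf_noise_band = hf_noise_band,
                 am_depth = am_depth, am_rate_hz = am_rate_hz,
                 duration_s = duration_s, sample_rate = sample_rate),
            class = "synth_params")
}

#' Quasi-periodic glottal excitation
#'
#' Generates a train of Rosenberg-style smooth glottal flow pulses. Each
#' cycle's period is the nominal period perturbed multiplicatively by
#' Gaussian noise scaled to `jitter_pct`, and each cycle's amplitude by
#' `shimmer_pct`. The pulse occupies the first 56% of the cycle (40% opening,
#' 16% closing); the remainder is the closed phase at exactly zero, so cycle
#' onsets are recoverable from the waveform.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Numeric vector of `round(duration_s * sample_rate)` samples.
#' @export
glottal_source <- function(params, seed = 1) {
  set.seed(seed)
  fs <- params$sample_rate
  n <- round(params$duration_s * fs)
  t0 <- fs / params$f0_hz
  out <- numeric(n)
  pos <- 0
  while (pos < n) {
    tc <- max(8, round(t0 * (1 + params$jitter_pct / 100 * stats::rnorm(1))))
    amp <- max(0.05, 1 + params$shimmer_pct / 100 * stats::rnorm(1))
    tp <- max(2, round(0.40 * tc))
    tn <- max(1, round(0.16 * tc))
    tt <- seq_len(tc) - 1
    pulse <- numeric(tc)
    pulse[tt < tp] <- 0.5 * (1 - cos(pi * tt[tt < tp] / tp))
    cl <- tt >= tp & tt < tp + tn
    pulse[cl] <- cos(pi * (tt[cl] - tp) / (2 * tn))
    take <- min(tc, n - pos)
    out[pos + seq_len(take)] <- amp * pulse[seq_len(take)]
    pos <- pos + tc
  }
  out
}

#' Vocal-tract resonance filter
#'
#' Cascade of second-order resonators (one per formant) with pole radius
#' `exp(-pi * bw / fs)`, each normalized to unit DC gain. For broadband
#' excitation the output spectrum shows local maxima near the formant
#' centers with approximately the requested -3 dB bandwidths.
#'
#' @param excitation Numeric excitation sequence.
#' @param formants List of `c(center_hz, bandwidth_hz)` pairs.
#' @param sample_rate Sample rate in Hz.
#' @return Filtered numeric vector of the same length.
#' @export
formant_filter <- function(excitation, formants, sample_rate = 16000) {
  y <- excitation
  for (fm in formants) {
    f <- fm[1]; bw <- fm[2]
    if (bw <= 0) stop("formant bandwidth must be positive")
    if (f >= sample_rate / 2) stop("formant center above Nyquist")
    r <- exp(-pi * bw / sample_rate)
    a1 <- 2 * r * cos(2 * pi * f / sample_rate)
    a2 <- -r^2
    g <- 1 - a1 - a2
    y <- as.numeric(signal::filter(g, c(1, -a1, -a2), y))
  }
  y
}

#' Class presets of the vowel synthesizer
#'
#' The per-class parameter overrides implementing the qualitative disorder
#' signatures (see [synth_vowel()]). Exposed as data, not hidden constants,
#' so studies can inspect or re-export them (e.g. via [yaml::write_yaml()]).
#'
#' @return Named list of per-class override lists.
#' @export
class_presets <- function() list(
  Normal = list(jitter_pct = 0.4, shimmer_pct = 2, hf_noise_db = -45,
                am_depth = 0),
  FD = list(jitter_pct = 2.5, shimmer_pct = 8, hf_noise_db = -35,
            am_depth = 0),
  Neo = list(jitter_pct = 1.2, shimmer_pct = 5, hf_noise_db = -10,
             am_depth = 0.1),
  Pho = list(jitter_pct = 1.5, shimmer_pct = 5, hf_noise_db = -22,
             am_depth = 0.1),
  VP = list(jitter_pct = 1.5, shimmer_pct = 6, hf_noise_db = -35,
            am_depth = 0.7, am_rate_hz = 2.5))

#' Synthesize one labeled sustained vowel
#'
#' Applies the class preset for `label` (overridable), builds the glottal
#' source, filters it through the /a/ formant cascade, applies the lip
#' radiation characteristic (first difference, so the spectrum is dominated
#' by the first formant rather than the fundamental, as in recorded
#' pressure waveforms), adds high-frequency noise at the preset level,
#' imposes the slow amplitude modulation envelope, and peak-normalizes to
#' 0.9 so the output is clip free. A small per-utterance
#' fundamental-frequency offset (log-normal, 5%) provides speaker-like
#' variation.
#'
#' @param label One of [voice_classes()].
#' @param overrides Named list of [synth_params()] fields overriding the
#'   class preset.
#' @param seed Integer seed; output is deterministic given
#'   `(label, overrides, seed)`.
#' @param utterance_id Identifier stored with the waveform.
#' @return A `labeled_waveform`: list with `samples`, `sample_rate`, `label`,
#'   `utterance_id`.
#' @export
synth_vowel <- function(label, overrides = list(), seed = 1,
                        utterance_id = sprintf("%s_%06d", label, seed)) {
  if (!label %in% voice_classes()) stop("unknown label: ", label)
  args <- utils::modifyList(class_presets()[[label]], overrides)
  params <- do.call(synth_params, args)
  set.seed(seed)
  f0 <- params$f0_hz * exp(stats::rnorm(1, 0, 0.05))
  src_seed <- sample.int(.Machine$integer.max - 1L, 1)
  params$f0_hz <- f0
  src <- glottal_source(params, src_seed)
  voiced <- formant_filter(src, params$formants, params$sample_rate)
  voiced <- c(0, diff(voiced))       # lip radiation: differentiate the flow
  fs <- params$sample_rate
  n <- length(voiced)
  noise <- stats::rnorm(n)
  bd <- params$hf_noise_band
  flt <- if (bd[2] >= fs / 2 - 1e-9)
    signal::butter(4, bd[1] / (fs / 2), "high")
  else
    signal::butter(4, bd / (fs / 2), "pass")
  noise <- as.numeric(signal::filter(flt, noise))
  rms <- function(x) sqrt(mean(x^2))
  noise <- noise / max(rms(noise), 1e-12) *
    rms(voiced) * 10^(params$hf_noise_db / 20)
  x <- voiced + noise
  if (params$am_depth > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    env <- 1 - params$am_depth *
      (0.5 + 0.5 * sin(2 * pi * params$am_rate_hz * seq_len(n) / fs + phase))
    x <- x * env
  }
  x <- x / max(abs(x)) * 0.9
  structure(list(samples = x, sample_rate = fs, label = label,
                 utterance_id = utterance_id),
            class = "labeled_waveform")
}

#' Generate an in-memory labeled vowel set
#'
#' @param n_per_class Named integer vector/list mapping labels to counts.
#' @param seed Master seed; per-utterance seeds are drawn from it.
#' @param overrides Named list of parameter overrides applied to all classes,
#'   or a list of such lists keyed by class label for per-class overrides.
#' @return List of `labeled_waveform` objects.
#' @export
make_waveforms <- function(n_per_class, seed = 1, overrides = list()) {
  labels <- names(n_per_class)
  if (is.null(labels) || !all(labels %in% voice_classes()))
    stop("n_per_class must be named by valid class labels")
  per_class <- length(overrides) > 0 && all(names(overrides) %in% voice_classes())
  set.seed(seed)
  total <- sum(unlist(n_per_class))
  seeds <- sample.int(.Machine$integer.max - 1L, max(total, 1L))
  out <- vector("list", total)
  i <- 0L
  for (lab in labels) {
    ov <- if (per_class) overrides[[lab]] %||% list() else overrides
    for (j in seq_len(n_per_class[[lab]])) {
      i <- i + 1L
      out[[i]] <- synth_vowel(lab, ov, seeds[i],
                              utterance_id = sprintf("%s_%03d", lab, j))
    }
  }
  out
}

#' Write a synthetic dataset to disk with a CSV manifest
#'
#' Synthesizes `n_per_class` vowels per label, writes each as a PCM 16-bit
#' mono WAV under `out_dir`, and writes `manifest.csv` with the header
#' `utterance_id,path,label`. Byte-identical output for identical inputs.
#'
#' @inheritParams make_waveforms
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (invisibly carries the manifest path as
#'   attribute `path`).
#' @export
make_dataset <- function(n_per_class, seed = 1, out_dir,
                         overrides = list()) {
  if (any(unlist(n_per_class) < 0)) stop("counts must be nonnegative")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  waves <- if (sum(unlist(n_per_class)) > 0)
    make_waveforms(n_per_class, seed, overrides) else list()
  manifest <- data.frame(
    utterance_id = vapply(waves, `[[`, "", "utterance_id"),
    path = vapply(waves, function(w)
      file.path(out_dir, paste0(w$utterance_id, ".wav")), ""),
    label = vapply(waves, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  for (w in waves)
    write_wav(w$samples, w$sample_rate,
              file.path(out_dir, paste0(w$utterance_id, ".wav")))
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  attr(manifest, "path") <- mpath
  manifest
}

#' Load the waveforms referenced by a manifest
#'
#' @param manifest Data frame with `utterance_id`, `path`, `label` columns,
#'   or the path of such a CSV.
#' @return List of `labeled_waveform` objects.
#' @export
load_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    wv <- read_wav(manifest$path[i])
    structure(list(samples = wv$samples, sample_rate = wv$sample_rate,
                   label = manifest$label[i],
                   utterance_id = manifest$utterance_id[i]),
              class = "labeled_waveform")
  })
}

#' @export
print.labeled_waveform <- function(x, ...) {
  cat(sprintf("labeled waveform %s [%s]: %.2f s at %g Hz, peak %.3f\n",
              x$utterance_id, x$label, length(x$samples) / x$sample_rate,
              x$sample_rate, max(abs(x$samples))))
  invisible(x)
}
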