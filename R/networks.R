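#' Declarative network architecture description
#'
#' A `network_spec` fully describes one of the three model families: the
#' sinc-filterbank network (learnable band edges only in the first layer),
#' the 1-D convolutional baseline (a fully learnable first-layer kernel of
#' the same shape), and the 2-D convolutional baseline operating on a
#' log-magnitude spectrogram of each chunk. Deleting the `front_end` element
#' from a sinc spec and from the matching 1-D baseline spec leaves identical
#' objects: the two models differ only in their first layer.
#'
#' @param front_end List with a `type` field (`"sinc"`, `"conv1d"` or
#'   `"conv2d-spectrogram"`) plus front-end parameters.
#' @param conv_layers List of `c(channels, kernel, stride)` triples (1-D) or
#'   lists with `channels`, `kernel`, `stride` pairs (2-D).
#' @param pool Max-pool size per conv layer (scalar for 1-D, pair for 2-D).
#' @param fc_layers Integer vector of fully connected widths.
#' @param dropout_conv Dropout fraction(s) after conv layers.
#' @param dropout_fc Dropout fraction per FC layer.
#' @param activation Activation id (`"leaky_relu"`).
#' @param slope Negative slope of the leaky rectifier.
#' @param norm Normalization scheme (`"batch+layer"`).
#' @param n_classes Number of output classes (>= 2).
#' @param sample_rate Waveform sample rate in Hz.
#' @param chunk_s,shift_s Chunk length and shift in seconds used at training.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(front_end, conv_layers, pool, fc_layers,
                         dropout_conv, dropout_fc, activation = "leaky_relu",
                         slope = 0.01, norm = "batch+layer", n_classes,
                         sample_rate, chunk_s = 0.2, shift_s = 0.01) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (any(dropout_conv < 0 | dropout_conv >= 1) ||
      any(dropout_fc < 0 | dropout_fc >= 1))
    stop("dropout fractions must lie in [0, 1)")
  if (any(fc_layers < 1)) stop("fc node counts must be positive")
  structure(list(front_end = front_end, conv_layers = conv_layers,
                 pool = pool, fc_layers = as.integer(fc_layers),
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc,
                 activation = activation, slope = slope, norm = norm,
                 n_classes = as.integer(n_classes), sample_rate = sample_rate,
                 chunk_s = chunk_s, shift_s = shift_s),
            class = "network_spec")
}

#' Reference sinc-filterbank network architecture
#'
#' 80 sinc band-pass channels of 251 taps (160 learnable front-end scalars),
#' two stacked `[60, 5]` convolutional layers, three 2048-node fully
#' connected layers, leaky rectifier activations, batch plus layer
#' normalization between hidden layers, dropout 0.5 after convolutional and
#' 0.3 after fully connected layers, and a softmax head.
#'
#' @param n_classes Number of output classes.
#' @param sample_rate Sample rate in Hz.
#' @param chunk_s,shift_s Chunk length/shift in seconds.
#' @return A `network_spec`.
#' @export
default_sincnet_spec <- function(n_classes, sample_rate,
                                 chunk_s = 0.2, shift_s = 0.01) {
  network_spec(
    front_end = list(type = "sinc", n_filters = 80L, filter_len = 251L,
                     stride = 1L, window = "hamming",
                     min_low_hz = 50, min_band_hz = 50),
    conv_layers = list(c(60L, 5L, 1L), c(60L, 5L, 1L)), pool = 3L,
    fc_layers = c(2048L, 2048L, 2048L),
    dropout_conv = 0.5, dropout_fc = c(0.3, 0.3, 0.3),
    n_classes = n_classes, sample_rate = sample_rate,
    chunk_s = chunk_s, shift_s = shift_s)
}

#' Reference 1-D convolutional baseline
#'
#' Identical stack to [default_sincnet_spec()] except that the first layer is
#' a fully learnable `[80, 251]` convolution instead of parametrized sinc
#' band-pass kernels.
#'
#' @inheritParams default_sincnet_spec
#' @return A `network_spec`.
#' @export
default_cnn1d_spec <- function(n_classes, sample_rate,
                               chunk_s = 0.2, shift_s = 0.01) {
  spec <- default_sincnet_spec(n_classes, sample_rate, chunk_s, shift_s)
  spec$front_end <- list(type = "conv1d", channels = 80L, kernel = 251L,
                         stride = 1L)
  spec
}

#' Reference 2-D convolutional baseline
#'
#' Consumes a log-magnitude spectrogram of each chunk (25 ms window, 10 ms
#' hop). Three convolutional layers with channel/kernel/stride
#' `[80, (3,3), (3,3)]`, `[60, (3,3), (3,3)]`, `[60, (3,3), (3,3)]`, each
#' followed by (3,3) max-pooling and batch plus layer normalization; dropout
#' 0.5 and 0.4 on the last two conv layers; then three 2048-node fully
#' connected layers with dropout 0.3, 0.2, 0.2.
#'
#' @inheritParams default_sincnet_spec
#' @return A `network_spec`.
#' @export
default_cnn2d_spec <- function(n_classes, sample_rate,
                               chunk_s = 0.2, shift_s = 0.01) {
  network_spec(
    front_end = list(type = "conv2d-spectrogram",
                     stft = list(win_s = 0.025, hop_s = 0.010, n_fft = 512L)),
    conv_layers = list(
      list(channels = 80L, kernel = c(3L, 3L), stride = c(3L, 3L)),
      list(channels = 60L, kernel = c(3L, 3L), stride = c(3L, 3L)),
      list(channels = 60L, kernel = c(3L, 3L), stride = c(3L, 3L))),
    pool = c(3L, 3L), fc_layers = c(2048L, 2048L, 2048L),
    dropout_conv = c(0, 0.5, 0.4), dropout_fc = c(0.3, 0.2, 0.2),
    n_classes = n_classes, sample_rate = sample_rate,
    chunk_s = chunk_s, shift_s = shift_s)
}

#' Compact desk-scale architectures
#'
#' Reduced variants of the reference architectures (24 sinc channels of 101
#' taps with a strided front end, two 32-channel convolutions, two 48-node
#' fully connected layers, non-overlapping 200 ms chunks) sized so that the
#' bundled synthetic experiments train in minutes on one CPU core while
#' keeping the structural contrast between the sinc and free-kernel front
#' ends.
#'
#' @inheritParams default_sincnet_spec
#' @return A `network_spec`.
#' @export
compact_sincnet_spec <- function(n_classes, sample_rate = 16000,
                                 chunk_s = 0.2, shift_s = 0.2) {
  network_spec(
    front_end = list(type = "sinc", n_filters = 24L, filter_len = 101L,
                     stride = 4L, window = "hamming",
                     min_low_hz = 50, min_band_hz = 50),
    conv_layers = list(c(32L, 5L, 1L), c(32L, 5L, 1L)), pool = 3L,
    fc_layers = c(48L, 48L), dropout_conv = 0.2, dropout_fc = c(0.2, 0.2),
    n_classes = n_classes, sample_rate = sample_rate,
    chunk_s = chunk_s, shift_s = shift_s)
}

#' @rdname compact_sincnet_spec
#' @export
compact_cnn1d_spec <- function(n_classes, sample_rate = 16000,
                               chunk_s = 0.2, shift_s = 0.2) {
  spec <- compact_sincnet_spec(n_classes, sample_rate, chunk_s, shift_s)
  spec$front_end <- list(type = "conv1d", channels = 24L, kernel = 101L,
                         stride = 4L)
  spec
}

norm_block <- function(channels, norm) {
  if (norm == "batch+layer") list(bn_layer_new(channels), ln_layer_new(channels))
  else if (norm == "none") list()
  else stop("unknown norm scheme: ", norm)
}

#' Build a trainable model from a network spec
#'
#' Instantiates every layer (front end, convolution/pool/normalization
#' blocks, fully connected stack, softmax head) with freshly initialized
#' parameters. Initialization draws from the R random number generator, so
#' `set.seed()` before building makes the model reproducible.
#'
#' @param spec A `network_spec`.
#' @param chunk_len Chunk length in samples (default derived from the spec's
#'   `chunk_s` and `sample_rate`).
#' @return An object of class `voice_model`.
#' @export
build_model <- function(spec, chunk_len = round(spec$chunk_s * spec$sample_rate)) {
  fe <- spec$front_end
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  dc <- rep(spec$dropout_conv, length.out = length(spec$conv_layers) + 1L)

  if (fe$type %in% c("sinc", "conv1d")) {
    t_len <- chunk_len
    if (fe$type == "sinc") {
      add(sinc_layer_new(fe$n_filters, fe$filter_len, spec$sample_rate,
                         fe$stride, fe$window, fe$min_low_hz, fe$min_band_hz))
      ch <- fe$n_filters; k <- fe$filter_len; s <- fe$stride
    } else {
      add(list(type = "conv1d", stride = fe$stride,
               params = list(w = he_init(fe$channels, fe$kernel),
                             b = rep(0, fe$channels))))
      ch <- fe$channels; k <- fe$kernel; s <- fe$stride
    }
    t_len <- (t_len - k) %/% s + 1L
    add(list(type = "maxpool1d", pool = spec$pool))
    t_len <- t_len %/% spec$pool
    for (l in norm_block(ch, spec$norm)) add(l)
    add(list(type = "leaky_relu", slope = spec$slope))
    add(list(type = "dropout", p = dc[1]))
    for (i in seq_along(spec$conv_layers)) {
      cl <- spec$conv_layers[[i]]
      add(list(type = "conv1d", stride = cl[3],
               params = list(w = he_init(cl[1], ch * cl[2]), b = rep(0, cl[1]))))
      t_len <- (t_len - cl[2]) %/% cl[3] + 1L
      ch <- cl[1]
      add(list(type = "maxpool1d", pool = spec$pool))
      t_len <- t_len %/% spec$pool
      for (l in norm_block(ch, spec$norm)) add(l)
      add(list(type = "leaky_relu", slope = spec$slope))
      add(list(type = "dropout", p = dc[i + 1L]))
    }
    flat <- t_len * ch
  } else if (fe$type == "conv2d-spectrogram") {
    win <- round(fe$stft$win_s * spec$sample_rate)
    hop <- round(fe$stft$hop_s * spec$sample_rate)
    add(list(type = "stft2d", win_len = win, hop = hop, n_fft = fe$stft$n_fft))
    h <- fe$stft$n_fft %/% 2 + 1L
    w_ <- max(1L, (chunk_len - win) %/% hop + 1L)
    ch <- 1L
    for (i in seq_along(spec$conv_layers)) {
      cl <- spec$conv_layers[[i]]
      kh <- cl$kernel[1]; kw <- cl$kernel[2]
      add(list(type = "conv2d", kernel = cl$kernel, stride = cl$stride,
               params = list(w = he_init(cl$channels, ch * kh * kw),
                             b = rep(0, cl$channels))))
      h <- (max(h, kh) - kh) %/% cl$stride[1] + 1L
      w_ <- (max(w_, kw) - kw) %/% cl$stride[2] + 1L
      ch <- cl$channels
      add(list(type = "maxpool2d", pool = spec$pool))
      h <- max(1L, h %/% min(spec$pool[1], h))
      w_ <- max(1L, w_ %/% min(spec$pool[2], w_))
      for (l in norm_block(ch, spec$norm)) add(l)
      add(list(type = "leaky_relu", slope = spec$slope))
      add(list(type = "dropout", p = dc[i]))
    }
    flat <- h * w_ * ch
  } else stop("unknown front end type: ", fe$type)

  add(list(type = "flatten"))
  n_in <- flat
  for (i in seq_along(spec$fc_layers)) {
    n_out <- spec$fc_layers[i]
    add(list(type = "dense",
             params = list(w = he_init(n_out, n_in), b = rep(0, n_out))))
    for (l in norm_block(n_out, spec$norm)) add(l)
    add(list(type = "leaky_relu", slope = spec$slope))
    add(list(type = "dropout", p = spec$dropout_fc[i]))
    n_in <- n_out
  }
  add(list(type = "dense",
           params = list(w = he_init(spec$n_classes, n_in),
                         b = rep(0, spec$n_classes))))
  structure(list(spec = spec, layers = layers, chunk_len = as.integer(chunk_len),
                 class_order = NULL),
            class = "voice_model")
}

#' Count learnable parameters of a built model
#'
#' @param model A `voice_model`.
#' @param front_only Count only the first (front-end) layer.
#' @return Integer scalar.
#' @export
count_params <- function(model, front_only = FALSE) {
  layers <- if (front_only) model$layers[1] else model$layers
  if (front_only && layers[[1]]$type == "stft2d") layers <- model$layers[2]
  sum(vapply(layers, function(l)
    if (is.null(l$params)) 0L else sum(vapply(l$params, length, 0L)), 0L))
}

#' Symbolic parameter count of an architecture
#'
#' Computes the learnable scalar count directly from the declarative spec
#' (front end, convolution shapes, flatten width, fully connected widths and
#' normalization affine pairs) without building any arrays; used to audit
#' built models.
#'
#' @param spec A `network_spec`.
#' @param chunk_len Chunk length in samples.
#' @return Integer scalar.
#' @export
spec_param_count <- function(spec, chunk_len = round(spec$chunk_s * spec$sample_rate)) {
  fe <- spec$front_end
  nrm <- function(ch) if (spec$norm == "batch+layer") 4L * ch else 0L
  total <- 0L
  if (fe$type %in% c("sinc", "conv1d")) {
    if (fe$type == "sinc") {
      total <- total + 2L * fe$n_filters
      ch <- fe$n_filters; k <- fe$filter_len; s <- fe$stride
    } else {
      total <- total + fe$channels * fe$kernel + fe$channels
      ch <- fe$channels; k <- fe$kernel; s <- fe$stride
    }
    t_len <- ((chunk_len - k) %/% s + 1L) %/% spec$pool
    total <- total + nrm(ch)
    for (cl in spec$conv_layers) {
      total <- total + cl[1] * ch * cl[2] + cl[1] + nrm(cl[1])
      t_len <- ((t_len - cl[2]) %/% cl[3] + 1L) %/% spec$pool
      ch <- cl[1]
    }
    flat <- t_len * ch
  } else {
    win <- round(fe$stft$win_s * spec$sample_rate)
    hop <- round(fe$stft$hop_s * spec$sample_rate)
    h <- fe$stft$n_fft %/% 2 + 1L
    w_ <- max(1L, (chunk_len - win) %/% hop + 1L)
    ch <- 1L
    for (cl in spec$conv_layers) {
      kh <- cl$kernel[1]; kw <- cl$kernel[2]
      total <- total + cl$channels * ch * kh * kw + cl$channels + nrm(cl$channels)
      h <- (max(h, kh) - kh) %/% cl$stride[1] + 1L
      w_ <- (max(w_, kw) - kw) %/% cl$stride[2] + 1L
      ch <- cl$channels
      h <- max(1L, h %/% min(spec$pool[1], h))
      w_ <- max(1L, w_ %/% min(spec$pool[2], w_))
    }
    flat <- h * w_ * ch
  }
  n_in <- flat
  for (n_out in spec$fc_layers) {
    total <- total + n_out * n_in + n_out + nrm(n_out)
    n_in <- n_out
  }
  as.integer(total + spec$n_classes * n_in + spec$n_classes)
}

check_chunk <- function(model, chunk) {
  if (length(chunk) != model$chunk_len)
    stop("chunk length ", length(chunk), " does not match the configured ",
         model$chunk_len)
  if (any(!is.finite(chunk))) stop("chunk contains non-finite values")
}

# Batched inference over a (T, 1, B) array of chunks.
predict_chunk_batch <- function(model, x) {
  softmax_cols(model_forward(model, x, training = FALSE)$logits)
}

#' Class posterior for one chunk
#'
#' Runs the model in inference mode (dropout off, normalization using
#' running statistics) on a single normalized chunk and returns the softmax
#' posterior over classes.
#'
#' @param model A `voice_model`.
#' @param chunk Numeric vector of length `model$chunk_len`.
#' @return Numeric probability vector summing to one (named by class if the
#'   model carries a class order).
#' @export
predict_chunk <- function(model, chunk) {
  check_chunk(model, chunk)
  p <- drop(predict_chunk_batch(model, array(chunk, c(length(chunk), 1L, 1L))))
  if (!is.null(model$class_order)) names(p) <- model$class_order
  p
}

#' Pre-softmax embedding of one chunk
#'
#' Returns the activation vector feeding the softmax head (the utterance
#' level feature used for the t-SNE analyses), computed in inference mode.
#'
#' @inheritParams predict_chunk
#' @return Numeric vector of length equal to the last fully connected width.
#' @export
extract_embedding <- function(model, chunk) {
  check_chunk(model, chunk)
  fw <- model_forward(model, array(chunk, c(length(chunk), 1L, 1L)),
                      training = FALSE)
  drop(fw$embedding)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network spec: %s front end, %d conv layer(s), FC [%s], %d classes\n",
              x$front_end$type, length(x$conv_layers),
              paste(x$fc_layers, collapse = ", "), x$n_classes))
  invisible(x)
}

#' @export
print.voice_model <- function(x, ...) {
  cat(sprintf("voice model: %s front end, %d layers, %d parameters, chunk %d samples\n",
              x$spec$front_end$type, length(x$layers), count_params(x),
              x$chunk_len))
  invisible(x)
}

#' Filterbank of a model's sinc front end
#'
#' Extracts the (possibly trained) sinc filterbank from a model's first
#' layer, e.g. to inspect learned bands with [cutoffs()] or export them
#' with [write_filterbank()].
#'
#' @param model A `voice_model` with a sinc front end.
#' @return A `sinc_filterbank`.
#' @export
filterbank <- function(model) {
  if (!inherits(model, "voice_model") ||
      model$layers[[1]]$type != "sinc_conv")
    stop("model does not have a sinc front end")
  sinc_layer_bank(model$layers[[1]])
}

#' Serialize / read a network spec as YAML
#'
#' @param spec A `network_spec`.
#' @param path File path.
#' @return `read_network_spec` returns a `network_spec`.
#' @export
write_network_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  structure(yaml::read_yaml(path), class = "network_spec")
}
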