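# Internal layer engine: forward/backward passes over plain-list layers.
#
# Activation layouts:
#   1-D stage:  array (time, channels, batch)
#   2-D stage:  array (height, width, channels, batch)
#   dense stage: matrix (features, batch)
#
# Each layer is a list with a `type` field, an optional `params` list of
# numeric arrays (the learnable state), and configuration fields. Gradients
# returned by `layer_backward()` mirror `params` by name.

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

# --- sinc front end -------------------------------------------------------

sinc_layer_new <- function(n_filters, filter_len, sample_rate, stride = 1L,
                           window = "hamming", min_low_hz = 50, min_band_hz = 50) {
  bank <- init_filterbank(n_filters, sample_rate, "mel", filter_len, window,
                          min_low_hz, min_band_hz)
  list(type = "sinc_conv", filter_len = as.integer(filter_len),
       sample_rate = sample_rate, stride = as.integer(stride),
       window = window, win = sinc_window(filter_len, window),
       offsets = seq.int(-(filter_len - 1) / 2, (filter_len - 1) / 2),
       min_low_hz = min_low_hz, min_band_hz = min_band_hz,
       params = list(raw_low = bank$raw_low, raw_band = bank$raw_band))
}

sinc_layer_kernels <- function(layer) {
  fs <- layer$sample_rate
  ct <- constrain_cutoffs(layer$params$raw_low, layer$params$raw_band,
                          layer$min_low_hz, layer$min_band_hz, fs)
  n <- layer$offsets
  lp <- function(fn) {
    m <- sin(2 * pi * outer(fn, n)) / rep(pi * n, each = length(fn))
    m[, n == 0] <- 2 * fn
    m
  }
  k <- (lp(ct$f2 / fs) - lp(ct$f1 / fs)) * rep(layer$win, each = length(ct$f1))
  list(k = k, f1 = ct$f1, f2 = ct$f2)
}

sinc_layer_bank <- function(layer) {
  structure(list(
    n_filters = length(layer$params$raw_low), filter_len = layer$filter_len,
    sample_rate = layer$sample_rate, window = layer$window,
    min_low_hz = layer$min_low_hz, min_band_hz = layer$min_band_hz,
    raw_low = layer$params$raw_low, raw_band = layer$params$raw_band),
    class = "sinc_filterbank")
}

# --- forward --------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    sinc_conv = {
      kk <- sinc_layer_kernels(layer)
      y <- conv1d_fwd(x, kk$k, layer$stride)
      list(y = y, cache = list(x = x, kk = kk), layer = layer)
    },
    conv1d = {
      y <- conv1d_fwd(x, layer$params$w, layer$stride)
      y <- y + rep(layer$params$b, each = dim(y)[1])
      list(y = y, cache = list(x = x), layer = layer)
    },
    maxpool1d = {
      r <- maxpool1d_fwd(x, layer$pool)
      list(y = r$y, cache = list(idx = r$idx, T = dim(x)[1]), layer = layer)
    },
    stft2d = {
      y <- stft_batch(x, layer$win_len, layer$hop, layer$n_fft)
      list(y = y, cache = NULL, layer = layer)
    },
    conv2d = {
      d <- dim(x); kh <- layer$kernel[1]; kw <- layer$kernel[2]
      if (d[1] < kh || d[2] < kw) {           # zero-pad tiny maps to kernel size
        xp <- array(0, c(max(d[1], kh), max(d[2], kw), d[3], d[4]))
        xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
        x <- xp
      }
      y <- conv2d_fwd(x, layer$params$w, kh, kw, layer$stride[1], layer$stride[2])
      y <- y + rep(layer$params$b, each = dim(y)[1] * dim(y)[2])
      list(y = y, cache = list(x = x, orig_dim = d), layer = layer)
    },
    maxpool2d = {
      d <- dim(x)
      ph <- min(layer$pool[1], d[1]); pw <- min(layer$pool[2], d[2])
      r <- maxpool2d_fwd(x, ph, pw)
      list(y = r$y, cache = list(idx = r$idx, H = d[1], W = d[2], ph = ph, pw = pw),
           layer = layer)
    },
    batchnorm = {
      bn_forward(layer, x, training)
    },
    layernorm = {
      ln_forward(layer, x)
    },
    leaky_relu = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$slope * x[neg]
      list(y = y, cache = list(neg = neg), layer = layer)
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- array(stats::runif(length(x)) >= layer$p, dim = dim(x)) / (1 - layer$p)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else list(y = x, cache = list(mask = NULL), layer = layer)
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, ncol = d[length(d)]), cache = list(d = d), layer = layer)
    },
    dense = {
      list(y = layer$params$w %*% x + layer$params$b, cache = list(x = x),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    sinc_conv = {
      kk <- cache$kk
      r <- conv1d_bwd(cache$x, kk$k, gy, layer$stride)
      fs <- layer$sample_rate
      n <- layer$offsets
      wrep <- rep(layer$win, each = length(kk$f1))
      dK2 <- 2 * cos(2 * pi * outer(kk$f2 / fs, n)) * wrep
      dK1 <- -2 * cos(2 * pi * outer(kk$f1 / fs, n)) * wrep
      gf2 <- rowSums(r$gw * dK2) / fs
      gf1 <- rowSums(r$gw * dK1) / fs
      rl <- layer$params$raw_low; rb <- layer$params$raw_band
      f1_free <- (layer$min_low_hz + abs(rl)) < fs / 2 - layer$min_band_hz
      f2_free <- (kk$f1 + layer$min_band_hz + abs(rb)) < fs / 2
      g_rl <- (gf1 + gf2 * f2_free) * sign(rl) * f1_free
      g_rb <- gf2 * f2_free * sign(rb)
      list(gx = r$gx, grads = list(raw_low = g_rl, raw_band = g_rb))
    },
    conv1d = {
      r <- conv1d_bwd(cache$x, layer$params$w, gy, layer$stride)
      gb <- apply(gy, 2, sum)
      list(gx = r$gx, grads = list(w = r$gw, b = gb))
    },
    maxpool1d = {
      list(gx = maxpool1d_bwd(cache$idx, gy, cache$T), grads = NULL)
    },
    stft2d = {
      list(gx = NULL, grads = NULL)  # input transform; gradient not propagated
    },
    conv2d = {
      r <- conv2d_bwd(cache$x, layer$params$w, gy,
                      layer$kernel[1], layer$kernel[2],
                      layer$stride[1], layer$stride[2])
      gb <- apply(gy, 3, sum)
      gx <- r$gx
      d <- cache$orig_dim
      if (any(dim(gx)[1:2] != d[1:2]))
        gx <- gx[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
      list(gx = gx, grads = list(w = r$gw, b = gb))
    },
    maxpool2d = {
      list(gx = maxpool2d_bwd(cache$idx, gy, cache$H, cache$W), grads = NULL)
    },
    batchnorm = bn_backward(layer, cache, gy),
    layernorm = ln_backward(layer, cache, gy),
    leaky_relu = {
      gx <- gy
      gx[cache$neg] <- layer$slope * gy[cache$neg]
      list(gx = gx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(gx = gy, grads = NULL)
      else list(gx = gy * cache$mask, grads = NULL)
    },
    flatten = {
      list(gx = array(gy, dim = cache$d), grads = NULL)
    },
    dense = {
      list(gx = crossprod(layer$params$w, gy),
           grads = list(w = tcrossprod(gy, cache$x), b = rowSums(gy)))
    },
    stop("unknown layer type: ", layer$type))
}

# --- normalization layers -------------------------------------------------

# Reshape an activation into an (observations x channels) matrix for
# per-channel batch statistics, and back.
act_to_mat <- function(x) {
  d <- dim(x)
  if (length(d) == 2) return(t(x))                       # dense: (B x F)
  if (length(d) == 3) {
    m <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])       # (T*B x C)
    return(m)
  }
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])           # (H*W*B x C)
}

mat_to_act <- function(m, d) {
  if (length(d) == 2) return(t(m))
  if (length(d) == 3) return(aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2)))
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_layer_new <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", eps = eps, momentum = momentum,
       running_mean = rep(0, channels), running_var = rep(1, channels),
       params = list(gamma = rep(1, channels), beta = rep(0, channels)))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- act_to_mat(x)
  if (training) {
    m <- colMeans(xm)
    v <- colMeans(xm^2) - m^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * m
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  } else {
    m <- layer$running_mean
    v <- layer$running_var
  }
  sd_ <- sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, m), 2, sd_, "/")
  y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  list(y = mat_to_act(y, d), cache = list(xhat = xhat, sd = sd_, d = d,
                                          training = training), layer = layer)
}

bn_backward <- function(layer, cache, gy) {
  d <- cache$d
  g <- act_to_mat(gy)
  xhat <- cache$xhat
  ggamma <- colSums(g * xhat)
  gbeta <- colSums(g)
  gxhat <- sweep(g, 2, layer$params$gamma, "*")
  if (cache$training) {
    nobs <- nrow(g)
    gx <- sweep(gxhat, 2, colMeans(gxhat)) -
      sweep(xhat, 2, colMeans(gxhat * xhat), "*")
    gx <- sweep(gx, 2, cache$sd, "/")
  } else {
    gx <- sweep(gxhat, 2, cache$sd, "/")
  }
  list(gx = mat_to_act(gx, d), grads = list(gamma = ggamma, beta = gbeta))
}

ln_layer_new <- function(channels, eps = 1e-5) {
  list(type = "layernorm", eps = eps,
       params = list(gamma = rep(1, channels), beta = rep(0, channels)))
}

# Per-sample normalization over all features of the sample; affine
# parameters are per channel (1-D/2-D stages) or per feature (dense stage).
ln_forward <- function(layer, x) {
  d <- dim(x)
  B <- d[length(d)]
  xm <- matrix(x, ncol = B)                 # one column per sample
  m <- colMeans(xm)
  v <- colMeans(xm^2) - m^2
  sd_ <- sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, m), 2, sd_, "/")
  gvec <- ln_affine_vec(layer$params$gamma, d)
  bvec <- ln_affine_vec(layer$params$beta, d)
  y <- xhat * gvec + bvec
  list(y = array(y, dim = d), cache = list(xhat = xhat, sd = sd_, d = d),
       layer = layer)
}

ln_affine_vec <- function(par, d) {
  if (length(d) == 2) return(par)                 # dense: per feature
  if (length(d) == 3) return(rep(par, each = d[1]))
  rep(par, each = d[1] * d[2])
}

ln_backward <- function(layer, cache, gy) {
  d <- cache$d
  B <- d[length(d)]
  g <- matrix(gy, ncol = B)
  xhat <- cache$xhat
  rs <- rowSums(g * xhat)
  rb <- rowSums(g)
  if (length(d) == 2) {
    ggamma <- rs; gbeta <- rb
  } else {
    per <- if (length(d) == 3) d[1] else d[1] * d[2]
    nch <- if (length(d) == 3) d[2] else d[3]
    ggamma <- colSums(matrix(rs, per, nch))
    gbeta <- colSums(matrix(rb, per, nch))
  }
  gxhat <- g * ln_affine_vec(layer$params$gamma, d)
  gx <- sweep(gxhat, 2, colMeans(gxhat)) -
    sweep(xhat, 2, colMeans(gxhat * xhat), "*")
  gx <- sweep(gx, 2, cache$sd, "/")
  list(gx = array(gx, dim = d), grads = list(gamma = ggamma, beta = gbeta))
}

# --- STFT front end for the 2-D baseline ----------------------------------

# Log-magnitude short-time Fourier transform of each chunk in the batch.
# Input (T, 1, B) -> output (n_fft/2 + 1, frames, 1, B).
stft_batch <- function(x, win_len, hop, n_fft) {
  if (n_fft < win_len) stop("stft n_fft must be at least the window length")
  d <- dim(x)
  n <- d[1]; B <- d[3]
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win_len) - 1) / (win_len - 1))
  nf <- max(1L, (n - win_len) %/% hop + 1L)
  nb <- n_fft %/% 2 + 1L
  out <- array(0, c(nb, nf, 1L, B))
  for (b in seq_len(B)) {
    for (f in seq_len(nf)) {
      seg <- x[seq.int((f - 1) * hop + 1, length.out = win_len), 1, b] * w
      sp <- stats::fft(c(seg, rep(0, n_fft - win_len)))
      out[, f, 1, b] <- log(Mod(sp[seq_len(nb)])^2 + 1e-8)
    }
  }
  out
}

# --- model-level passes ---------------------------------------------------

model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    if (i == length(model$layers)) embedding <- x      # input of the softmax head
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
  }
  list(logits = x, caches = caches, embedding = embedding, model = model)
}

model_backward <- function(model, caches, glogits) {
  grads <- vector("list", length(model$layers))
  gy <- glogits
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], gy)
    grads[i] <- list(r$grads)          # keep NULL placeholders for param-free layers
    gy <- r$gx
    if (is.null(gy)) break                  # reached a stop-gradient transform
  }
  grads
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy over a batch plus the gradient w.r.t. the logits.
xent_loss <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  ll <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  g <- p
  g[cbind(y, seq_len(B))] <- g[cbind(y, seq_len(B))] - 1
  list(loss = ll, glogits = g / B)
}

# --- Adam -----------------------------------------------------------------

adam_new <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- lapply(model$layers, function(l)
    if (is.null(l$params)) NULL
    else lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, st = st)
}

adam_step <- function(model, grads, opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      s <- opt$st[[i]][[nm]]
      s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
      s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
      opt$st[[i]][[nm]] <- s
      model$layers[[i]]$params[[nm]] <- model$layers[[i]]$params[[nm]] -
        opt$lr * (s$m / c1) / (sqrt(s$v / c2) + opt$eps)
    }
  }
  list(model = model, opt = opt)
}
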