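# Compact encoder-decoder reference model (U-Net-style skip connections),
# trained with hand-derived backpropagation. Convolutions run through the
# package's im2col+GEMM kernel; pooling, upsampling and activations are plain
# vectorized array operations. Arrays are laid out (H, W, C, N).

LRELU_SLOPE <- 0.1

lrelu <- function(x) lrelu_fw(x, LRELU_SLOPE)

lrelu_bw <- function(x_pre, g) lrelu_bw_cpp(x_pre, g, LRELU_SLOPE)

maxpool2 <- function(x) maxpool2_fw(x)

maxpool2_bw <- function(x, g) maxpool2_bw_cpp(x, g)

upsample2 <- function(x) upsample2_fw(x)

upsample2_bw <- function(g) upsample2_bw_cpp(g)

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

conv1x1_fw <- function(x, w, b) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  y <- matrix(xp, ncol = d[3L]) %*% w
  y <- sweep(y, 2L, b, "+")
  cout <- ncol(w)
  aperm(array(y, c(d[1L], d[2L], d[4L], cout)), c(1L, 2L, 4L, 3L))
}

conv1x1_bw <- function(x, w, g) {
  d <- dim(x)
  cout <- ncol(w)
  gp <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), ncol = cout)
  xp <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  gx <- gp %*% t(w)
  gx <- aperm(array(gx, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(gx = gx, gw = crossprod(xp, gp), gb = colSums(gp))
}

#' Define the reference segmentation model
#'
#' A compact encoder-decoder with skip connections: one 3x3 convolution +
#' leaky-ReLU per resolution level, channel widths doubling with depth, 2x2
#' max-pooling down and nearest-neighbour upsampling with skip concatenation
#' up, closed by a 1x1 convolution to a single-logit map. Deliberately small
#' so the full training loop runs on a CPU in minutes; `base_width` and
#' `levels` scale it up when heavier capacity is wanted, and the trainer
#' accepts any drop-in model implementing the same forward/backward contract.
#'
#' @param in_channels input image channels (3 for RGB).
#' @param base_width channels at the finest level; doubled at each deeper
#'   level.
#' @param levels number of resolution levels (`levels - 1` downsamplings);
#'   input height/width must be divisible by `2^(levels - 1)`.
#' @return a `seg_model` specification.
#' @export
seg_model <- function(in_channels = 3L, base_width = 4L, levels = 3L) {
  stopifnot(in_channels >= 1L, base_width >= 1L, levels >= 2L)
  widths <- base_width * 2L^(seq_len(levels) - 1L)
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 levels = as.integer(levels), widths = as.integer(widths)),
            class = "seg_model")
}

#' Initialize model parameters
#'
#' He-style initialization scaled to the fan-in of each 3x3 kernel; biases
#' start at zero except the output logit bias, which starts at -2 to encode
#' the background-dominant prior of lesion frames.
#'
#' @param model a [seg_model()].
#' @param seed integer seed; initialization is a pure function of it.
#' @return a [as_parameter_set()] parameter set.
#' @export
init_params <- function(model, seed) {
  stopifnot(inherits(model, "seg_model"))
  L <- model$levels
  w <- model$widths
  cin <- c(model$in_channels, w[-L])
  params <- list()
  with_local_seed(derive_seed(seed, "init"), {
    for (l in seq_len(L)) {
      sdv <- sqrt(2 / (9 * cin[l]))
      params[[sprintf("enc%d.w", l)]] <-
        array(rnorm(9 * cin[l] * w[l], sd = sdv), c(3L, 3L, cin[l], w[l]))
      params[[sprintf("enc%d.b", l)]] <- numeric(w[l])
    }
    for (l in rev(seq_len(L - 1L))) {
      cc <- w[l] + w[l + 1L]
      sdv <- sqrt(2 / (9 * cc))
      params[[sprintf("dec%d.w", l)]] <-
        array(rnorm(9 * cc * w[l], sd = sdv), c(3L, 3L, cc, w[l]))
      params[[sprintf("dec%d.b", l)]] <- numeric(w[l])
    }
    params[["out.w"]] <- matrix(rnorm(w[1L], sd = sqrt(2 / w[1L])), w[1L], 1L)
    params[["out.b"]] <- -2.0
  })
  as_parameter_set(params)
}

#' Model forward pass
#'
#' @param model a [seg_model()] or any object with a `model_forward` method.
#' @param params its parameter set.
#' @param x input array `(H, W, C, N)` with values in `[0, 1]`.
#' @param keep_cache retain intermediate activations for [model_backward()].
#' @return list with `logits` `(H, W, 1, N)` and (optionally) `cache`.
#' @export
model_forward <- function(model, params, x, keep_cache = FALSE) {
  UseMethod("model_forward")
}

# per-image, per-channel standardization: makes the network invariant to
# global brightness/gain differences between acquisition settings
standardize_input <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  mu <- colMeans(xm)
  sdv <- sqrt(pmax(colMeans(xm^2) - mu^2, 0)) + 1e-6
  xm <- sweep(sweep(xm, 2L, mu, "-"), 2L, sdv, "/")
  array(xm, d)
}

#' @export
model_forward.seg_model <- function(model, params, x, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[3L] != model$in_channels) {
    stop(sprintf("model_forward: expected (H, W, %d, N) input", model$in_channels))
  }
  down <- 2L^(model$levels - 1L)
  if (d[1L] %% down != 0L || d[2L] %% down != 0L) {
    stop(sprintf("model_forward: H and W must be divisible by %d", down))
  }
  L <- model$levels
  x <- standardize_input(x)
  cache <- list(x = x)
  a <- vector("list", L)   # post-activation encoder outputs
  pre <- vector("list", L) # pre-activation
  inp <- x
  for (l in seq_len(L)) {
    if (l > 1L) {
      cache[[sprintf("pool_in%d", l)]] <- inp
      inp <- maxpool2(inp)
    }
    if (keep_cache) {
      fwc <- conv3x3_fw_cache(inp, params[[sprintf("enc%d.w", l)]],
                              params[[sprintf("enc%d.b", l)]])
      z <- fwc$y
      cache[[sprintf("enc_col%d", l)]] <- fwc$col
    } else {
      z <- conv3x3_fw(inp, params[[sprintf("enc%d.w", l)]],
                      params[[sprintf("enc%d.b", l)]])
    }
    pre[[l]] <- z
    a[[l]] <- lrelu(z)
    inp <- a[[l]]
  }
  h <- a[[L]]
  for (l in rev(seq_len(L - 1L))) {
    u <- upsample2(h)
    cc <- concat_ch(a[[l]], u)
    if (keep_cache) {
      fwc <- conv3x3_fw_cache(cc, params[[sprintf("dec%d.w", l)]],
                              params[[sprintf("dec%d.b", l)]])
      z <- fwc$y
      cache[[sprintf("dec_col%d", l)]] <- fwc$col
    } else {
      z <- conv3x3_fw(cc, params[[sprintf("dec%d.w", l)]],
                      params[[sprintf("dec%d.b", l)]])
    }
    cache[[sprintf("dec_pre%d", l)]] <- z
    h <- lrelu(z)
    cache[[sprintf("dec_out%d", l)]] <- h
  }
  logits <- conv1x1_fw(h, params[["out.w"]], params[["out.b"]])
  if (keep_cache) {
    cache$enc_pre <- pre
    cache$enc_act <- a
    cache$head_in <- h
    list(logits = logits, cache = cache)
  } else {
    list(logits = logits)
  }
}

#' Model backward pass
#'
#' Backpropagates a gradient with respect to the logits through the network,
#' returning per-parameter gradients shaped exactly like the parameter set.
#'
#' @param model a [seg_model()].
#' @param params parameter set used in the forward pass.
#' @param cache cache returned by [model_forward()] with `keep_cache = TRUE`.
#' @param g_logits gradient of the loss with respect to the logits.
#' @return named list of gradients.
#' @export
model_backward <- function(model, params, cache, g_logits) {
  UseMethod("model_backward")
}

#' @export
model_backward.seg_model <- function(model, params, cache, g_logits) {
  L <- model$levels
  grads <- list()
  hb <- conv1x1_bw(cache$head_in, params[["out.w"]], g_logits)
  grads[["out.w"]] <- hb$gw
  grads[["out.b"]] <- hb$gb
  g <- hb$gx
  g_skip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    g <- lrelu_bw(cache[[sprintf("dec_pre%d", l)]], g)
    cb <- conv3x3_bw_col(cache[[sprintf("dec_col%d", l)]],
                         params[[sprintf("dec%d.w", l)]], g, TRUE)
    grads[[sprintf("dec%d.w", l)]] <- cb$gw
    grads[[sprintf("dec%d.b", l)]] <- cb$gb
    wl <- model$widths[l]
    g_skip[[l]] <- cb$gx[, , seq_len(wl), , drop = FALSE]
    g <- upsample2_bw(cb$gx[, , -seq_len(wl), , drop = FALSE])
  }
  # g now flows into the deepest encoder activation
  for (l in rev(seq_len(L))) {
    if (l < L) g <- g + g_skip[[l]]
    g <- lrelu_bw(cache$enc_pre[[l]], g)
    cb <- conv3x3_bw_col(cache[[sprintf("enc_col%d", l)]],
                         params[[sprintf("enc%d.w", l)]], g, l > 1L)
    grads[[sprintf("enc%d.w", l)]] <- cb$gw
    grads[[sprintf("enc%d.b", l)]] <- cb$gb
    if (l > 1L) {
      g <- cb$gx
      g <- maxpool2_bw(cache[[sprintf("pool_in%d", l)]], g)
    }
  }
  grads[names(params)]
}

#' Predict probability maps for a set of samples
#'
#' Runs the model over samples in mini-batches and returns per-sample
#' probability maps (plain sigmoid of the logits).
#'
#' @param model a [seg_model()].
#' @param params parameter set.
#' @param samples list of segmentation samples (see [make_phantom()]).
#' @param batch_size mini-batch size for the forward passes.
#' @return list of `(H, W)` probability matrices named by sample id.
#' @export
predict_prob <- function(model, params, samples, batch_size = 8L) {
  n <- length(samples)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- stack_images(samples[i:j])
    lg <- model_forward(model, params, x)$logits
    for (k in i:j) out[[k]] <- sigmoid(lg[, , 1L, k - i + 1L])
    i <- j + 1L
  }
  names(out) <- vapply(samples, function(s) s$id, character(1))
  out
}

# stack sample images into an (H, W, C, N) batch array
stack_images <- function(samples) {
  d <- dim(samples[[1L]]$image)
  x <- array(0, c(d[1L], d[2L], d[3L], length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- samples[[i]]$image
  x
}

# stack sample masks into an (H, W, 1, N) batch array
stack_masks <- function(samples) {
  d <- dim(samples[[1L]]$mask)
  y <- array(0, c(d[1L], d[2L], 1L, length(samples)))
  for (i in seq_along(samples)) y[, , 1L, i] <- samples[[i]]$mask
  y
}
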