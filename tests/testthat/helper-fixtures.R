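# Shared fixtures: small phantom datasets, a pluggable 2-parameter toy model,
# and an exhaustive sign-flip enumerator used as the Wilcoxon oracle.

tiny_phantoms <- function(n, size = 32L, seed = 42L, domain = "source", ...) {
  args <- list(image_size = size, n_images = n, seed = seed, domain = domain, ...)
  # scale the lesion rim with the frame so small fixtures remain placeable
  if (is.null(args$boundary_softness)) args$boundary_softness <- size / 32
  cfg <- do.call(phantom_config, args)
  make_dataset(cfg)
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(image_size = 32L, epochs = 2L, seed = 1L),
                            list(...))
  do.call(train_config, args)
}

# enumerate all 2^n sign assignments of the signed-rank null (average ranks,
# two-sided p = min(1, 2 * min(P(W <= w), P(W >= w))))
wilcoxon_brute_force <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

adamw_init_for_test <- function(params) prismseg:::adamw_init(params)

# minimal pluggable model: one logit per sample, logit = w * x + b, where x is
# the first-channel value of a single-pixel image
toy_linear_model <- function() {
  structure(list(in_channels = 3L), class = "toy_linear")
}

model_forward.toy_linear <- function(model, params, x, keep_cache = FALSE) {
  n <- dim(x)[4L]
  xv <- x[1L, 1L, 1L, ]
  logits <- array(params$w * xv + params$b, c(1L, 1L, 1L, n))
  out <- list(logits = logits)
  if (keep_cache) out$cache <- list(xv = xv)
  out
}

model_backward.toy_linear <- function(model, params, cache, g_logits) {
  g <- as.numeric(g_logits)
  list(w = sum(g * cache$xv), b = sum(g))
}

registerS3method("model_forward", "toy_linear", model_forward.toy_linear,
                 envir = asNamespace("prismseg"))
registerS3method("model_backward", "toy_linear", model_backward.toy_linear,
                 envir = asNamespace("prismseg"))

toy_sample <- function(xval, yval, id = "toy") {
  structure(list(id = id,
                 image = array(xval, c(1L, 1L, 3L)),
                 mask = matrix(yval, 1L, 1L)),
            class = "segmentation_sample")
}
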