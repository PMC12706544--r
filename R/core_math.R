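# Pure differentiable building blocks: activations and the three loss terms
# composing the training objective (soft-Dice + BCE + lambda * distillation MSE).

#' Numerically stable logistic sigmoid
#'
#' Maps real-valued logits to `(0, 1)` as `1 / (1 + exp(-x))`, computed in the
#' overflow-safe branch form so that inputs with magnitude up to several
#' hundred return exact 0/1-adjacent values instead of `NaN`.
#'
#' @param x numeric vector or array of logits; must be finite.
#' @return values in `(0, 1)` (0 or 1 only by floating underflow at extreme
#'   logits), same shape as `x`.
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(c(-1, 1)) # sums to 1
#' @export
sigmoid <- function(x) {
  if (any(is.na(x))) stop("sigmoid: NaN/NA logits are invalid")
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Temperature-scaled sigmoid
#'
#' `sigmoid(x / T)`. Temperatures above 1 soften the output towards 0.5,
#' producing the soft targets used for distillation; temperatures below 1
#' sharpen it towards a hard 0/1 map. `T = 1` reproduces [sigmoid()] exactly.
#'
#' @param x numeric vector or array of logits.
#' @param temperature positive scalar temperature.
#' @return values in `(0, 1)`, same shape as `x`.
#' @export
temp_sigmoid <- function(x, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0) {
    stop("temp_sigmoid: temperature must be a positive finite scalar")
  }
  if (temperature == 1) return(sigmoid(x))
  sigmoid(x / temperature)
}

check_same_shape <- function(a, b, what) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf(
      "%s: shape mismatch (%s vs %s)", what,
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ))
  }
}

# number of samples along the batch axis (4th dim), 1 for unbatched arrays
batch_size_of <- function(x) {
  d <- dim(x)
  if (!is.null(d) && length(d) == 4L) d[4L] else 1L
}

# iterate over per-sample slices as plain numeric vectors
split_batch <- function(x) {
  n <- batch_size_of(x)
  if (n == 1L) return(list(as.numeric(x)))
  m <- matrix(x, ncol = n)
  lapply(seq_len(n), function(i) m[, i])
}

#' Loss weights for the composite objective
#'
#' @param lambda_kd non-negative weight of the distillation term.
#' @param smooth_eps positive additive smoothing of the soft-Dice ratio
#'   (stabilises empty-mask batches; default 1).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_kd = 1.0, smooth_eps = 1.0) {
  stopifnot(is.numeric(lambda_kd), length(lambda_kd) == 1L, lambda_kd >= 0)
  stopifnot(is.numeric(smooth_eps), length(smooth_eps) == 1L, smooth_eps > 0)
  structure(list(lambda_kd = lambda_kd, smooth_eps = smooth_eps),
            class = "loss_weights")
}

#' Soft-Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)` computed per sample
#' and averaged over the batch (4th array dimension). Lies in `[0, 1]`; 0 for
#' a perfect hard prediction (up to the smoothing term) and 1 for disjoint
#' supports.
#'
#' @param pred probability map, entries in `[0, 1]`.
#' @param target binary mask with entries in `{0, 1}`, same shape.
#' @param smooth_eps positive smoothing constant added to numerator and
#'   denominator.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target, smooth_eps = 1.0) {
  check_same_shape(pred, target, "dice_loss")
  ps <- split_batch(pred)
  ys <- split_batch(target)
  vals <- mapply(function(p, y) {
    1 - (2 * sum(p * y) + smooth_eps) / (sum(p) + sum(y) + smooth_eps)
  }, ps, ys)
  mean(vals)
}

BCE_CLAMP <- 1e-7

#' Pixel-mean binary cross-entropy
#'
#' Mean over all pixels (and batch entries) of
#' `-(y * log(p) + (1 - y) * log(1 - p))`. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm, so exact 0/1 predictions are
#' handled rather than rejected.
#'
#' @param pred probability map.
#' @param target binary mask, same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, target) {
  check_same_shape(pred, target, "bce_loss")
  p <- clamp(as.numeric(pred), BCE_CLAMP, 1 - BCE_CLAMP)
  y <- as.numeric(target)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Distillation consistency loss (pixel-mean squared error)
#'
#' Mean squared difference between the student's and the teacher's
#' temperature-softened probability maps. Zero if and only if the maps are
#' identical; bounded by 1 for inputs in `(0, 1)`.
#'
#' @param student_soft,teacher_soft softened probability maps of equal shape.
#' @return non-negative scalar.
#' @export
kd_loss <- function(student_soft, teacher_soft) {
  check_same_shape(student_soft, teacher_soft, "kd_loss")
  mean((as.numeric(student_soft) - as.numeric(teacher_soft))^2)
}

#' Composite training loss
#'
#' Evaluates `L = L_Dice(sigmoid(z), y) + L_BCE(sigmoid(z), y) +
#' lambda * L_KD(soft(z), soft(z_teacher))` where the distillation term is
#' included only when `kd_active` is `TRUE`. Teacher logits are treated as a
#' constant target: no gradient is ever propagated to them (the returned
#' gradient is with respect to the student logits only).
#'
#' @param pred_logits student logit array.
#' @param target binary mask, same shape.
#' @param teacher_logits teacher logit array, required when `kd_active`.
#' @param temperature positive distillation temperature applied to the teacher
#'   (and to the student when `student_temperature` is `TRUE`).
#' @param weights a [loss_weights()] object.
#' @param kd_active logical; when `FALSE` the distillation branch is skipped
#'   entirely and the result equals the plain supervised loss.
#' @param student_temperature logical; soften the student logits with the same
#'   temperature as the teacher (default) or compare the plain-sigmoid student
#'   map against the softened teacher.
#' @param with_grad logical; also return the analytic gradient with respect to
#'   `pred_logits`.
#' @return a list with `total`, `dice`, `bce`, `kd` (NA when not applied),
#'   `kd_applied`, and `grad` when requested.
#' @export
total_loss <- function(pred_logits, target, teacher_logits = NULL,
                       temperature = 2.0, weights = loss_weights(),
                       kd_active = FALSE, student_temperature = TRUE,
                       with_grad = FALSE) {
  check_same_shape(pred_logits, target, "total_loss")
  if (kd_active && is.null(teacher_logits)) {
    stop("total_loss: kd_active requires teacher_logits")
  }
  p <- sigmoid(pred_logits)
  n_tot <- length(pred_logits)
  nb <- batch_size_of(pred_logits)

  dice <- dice_loss(p, target, weights$smooth_eps)
  bce <- bce_loss(p, target)

  use_kd <- kd_active && weights$lambda_kd > 0
  kd <- NA_real_
  s_soft <- t_soft <- NULL
  if (use_kd) {
    check_same_shape(pred_logits, teacher_logits, "total_loss (teacher)")
    s_soft <- if (student_temperature) temp_sigmoid(pred_logits, temperature) else p
    t_soft <- temp_sigmoid(teacher_logits, temperature)
    kd <- kd_loss(s_soft, t_soft)
  }
  total <- if (use_kd) dice + bce + weights$lambda_kd * kd else dice + bce

  out <- list(total = total, dice = dice, bce = bce, kd = kd,
              kd_applied = use_kd)
  if (with_grad) {
    eps <- weights$smooth_eps
    # soft-Dice gradient, per sample then averaged over the batch
    g_dice <- array(0, dim(pred_logits) %||% length(pred_logits))
    ps <- split_batch(p)
    ys <- split_batch(target)
    per <- length(ps[[1L]])
    for (i in seq_len(nb)) {
      pi <- ps[[i]]; yi <- ys[[i]]
      den <- sum(pi) + sum(yi) + eps
      num <- 2 * sum(pi * yi) + eps
      gd <- -(2 * yi * den - num) / den^2 / nb
      idx <- ((i - 1L) * per + 1L):(i * per)
      g_dice[idx] <- gd
    }
    g <- g_dice * p * (1 - p) + (p - as.numeric(target)) / n_tot
    if (use_kd) {
      tt <- if (student_temperature) temperature else 1
      g_kd <- 2 * (s_soft - t_soft) * s_soft * (1 - s_soft) / tt / n_tot
      g <- g + weights$lambda_kd * g_kd
    }
    dim(g) <- dim(pred_logits)
    out$grad <- g
  }
  out
}
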