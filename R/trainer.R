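# Three-mode training loop: plain supervised baseline ("base"), conventional
# self-distillation against the model's own cached soft predictions ("sd"),
# and momentum-teacher distillation ("prism"). AdamW optimization,
# validation-loss checkpointing, full per-purpose seed control.

#' Training configuration
#'
#' Defaults follow the experimental protocol of the study this package
#' implements: AdamW with a fixed learning rate of 1e-4, batch size 4, 30
#' epochs, a 90/10 train/validation split, checkpoint selection on the lowest
#' validation loss, momentum coefficient 0.90, and distillation delayed until
#' after the sixth training epoch. The distillation weight `lambda_kd = 1` and
#' temperature `temperature = 2` are package defaults (no published values
#' exist for them) and are recorded in every run snapshot.
#'
#' @param mode `"base"`, `"sd"` or `"prism"`.
#' @param learning_rate positive AdamW learning rate.
#' @param batch_size positive integer mini-batch size.
#' @param epochs positive integer number of epochs.
#' @param gamma EMA momentum coefficient in `[0, 1]`.
#' @param temperature positive distillation temperature.
#' @param lambda_kd non-negative distillation weight.
#' @param distill_start_epoch first 1-based epoch with an active distillation
#'   term.
#' @param val_fraction fraction of samples held out for validation.
#' @param image_size square input resolution the model expects.
#' @param seed master seed; every random component derives a named sub-seed
#'   from it.
#' @param student_temperature soften the student with the same temperature as
#'   the teacher inside the distillation term (default), or compare the
#'   plain-sigmoid student map against the softened teacher.
#' @param ema_warmup `"always"`: the teacher EMA runs from the first iteration
#'   while only the loss term is gated (default); `"after_start"`: the EMA
#'   itself also waits for `distill_start_epoch`.
#' @param sd_source `"per_sample_cache"`: the SD baseline regresses each
#'   sample onto its own most recent soft prediction (default);
#'   `"prev_batch"`: onto the previous mini-batch's soft predictions.
#' @param weight_decay AdamW decoupled weight decay.
#' @param smooth_eps soft-Dice smoothing constant.
#' @param base_width,levels size of the reference model built by the default
#'   model factory.
#' @return a `train_config` list.
#' @export
train_config <- function(mode = c("base", "sd", "prism"),
                         learning_rate = 1e-4, batch_size = 4L, epochs = 30L,
                         gamma = 0.90, temperature = 2.0, lambda_kd = 1.0,
                         distill_start_epoch = 7L, val_fraction = 0.10,
                         image_size = 256L, seed = 1L,
                         student_temperature = TRUE,
                         ema_warmup = c("always", "after_start"),
                         sd_source = c("per_sample_cache", "prev_batch"),
                         weight_decay = 1e-2, smooth_eps = 1.0,
                         base_width = 4L, levels = 3L) {
  mode <- match.arg(mode)
  ema_warmup <- match.arg(ema_warmup)
  sd_source <- match.arg(sd_source)
  stopifnot(
    learning_rate > 0, batch_size >= 1, epochs >= 1,
    gamma >= 0, gamma <= 1, temperature > 0, lambda_kd >= 0,
    distill_start_epoch >= 1, val_fraction > 0, val_fraction < 1,
    image_size >= 8, weight_decay >= 0, smooth_eps > 0
  )
  structure(list(
    mode = mode, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    gamma = gamma, temperature = temperature, lambda_kd = lambda_kd,
    distill_start_epoch = as.integer(distill_start_epoch),
    val_fraction = val_fraction, image_size = as.integer(image_size),
    seed = as.integer(seed), student_temperature = student_temperature,
    ema_warmup = ema_warmup, sd_source = sd_source,
    weight_decay = weight_decay, smooth_eps = smooth_eps,
    base_width = as.integer(base_width), levels = as.integer(levels)
  ), class = "train_config")
}

#' Deterministic train/validation split
#'
#' @param samples list of segmentation samples (>= 2).
#' @param val_fraction fraction in `(0, 1)` held out for validation; the
#'   validation size is `round(n * val_fraction)`, at least 1.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list with `train` and `val` sample lists (disjoint, exhaustive).
#' @export
split_dataset <- function(samples, val_fraction = 0.10, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("split_dataset: need at least 2 samples")
  stopifnot(val_fraction > 0, val_fraction < 1)
  n_val <- max(1L, as.integer(round(n * val_fraction)))
  if (n_val >= n) n_val <- n - 1L
  perm <- with_local_seed(derive_seed(seed, "split"), sample.int(n))
  list(train = samples[perm[(n_val + 1L):n]], val = samples[perm[seq_len(n_val)]])
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- lapply(params, function(a) {
    z <- a; z[] <- 0; z
  })
  list(m = zeros, v = zeros, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_step <- function(params, grads, opt, lr, weight_decay) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g * g
    step <- (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + opt$eps)
    params[[k]] <- params[[k]] - lr * (step + weight_decay * params[[k]])
  }
  list(params = params, opt = opt)
}

# ---- single training steps -------------------------------------------------

check_finite_loss <- function(components, ids) {
  if (!is.finite(components$total)) {
    stop(sprintf("non-finite training loss (%.4g) on batch [%s]",
                 components$total, paste(ids, collapse = ", ")))
  }
}

#' One supervised (base) training step
#'
#' A single AdamW step on the Dice + BCE loss of one mini-batch.
#'
#' @param model a [seg_model()] (or compatible model).
#' @param params current parameter set.
#' @param opt AdamW state from the previous step.
#' @param batch list of segmentation samples.
#' @param cfg a [train_config()].
#' @return list with updated `params`, `opt`, and the loss `components`.
#' @export
train_step_base <- function(model, params, opt, batch, cfg) {
  x <- stack_images(batch)
  y <- stack_masks(batch)
  fw <- model_forward(model, params, x, keep_cache = TRUE)
  w <- loss_weights(cfg$lambda_kd, cfg$smooth_eps)
  loss <- total_loss(fw$logits, y, weights = w, kd_active = FALSE,
                     with_grad = TRUE)
  check_finite_loss(loss, vapply(batch, `[[`, "", "id"))
  grads <- model_backward(model, params, fw$cache, loss$grad)
  upd <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
  list(params = upd$params, opt = upd$opt,
       components = loss[c("total", "dice", "bce", "kd", "kd_applied")])
}

#' One conventional self-distillation (SD) training step
#'
#' Supervised loss plus, when `warm` and a prior soft prediction is available,
#' the mean-squared consistency loss between the current softened prediction
#' and the stored one. The cache is refreshed afterwards with the current
#' (detached) soft maps. With `sd_source = "prev_batch"` the target is the
#' previous mini-batch's soft prediction instead of a per-sample store.
#'
#' @inheritParams train_step_base
#' @param cache an environment created by [sd_cache()].
#' @param warm logical; whether the consistency term is active this epoch.
#' @param epoch current 1-based epoch (recorded in the cache).
#' @return list with updated `params`, `opt`, loss `components`; the cache is
#'   updated in place.
#' @export
train_step_sd <- function(model, params, opt, batch, cfg, cache,
                          warm = TRUE, epoch = 1L) {
  x <- stack_images(batch)
  y <- stack_masks(batch)
  ids <- vapply(batch, `[[`, "", "id")
  fw <- model_forward(model, params, x, keep_cache = TRUE)
  w <- loss_weights(cfg$lambda_kd, cfg$smooth_eps)
  loss <- total_loss(fw$logits, y, weights = w, kd_active = FALSE,
                     with_grad = TRUE)
  g <- loss$grad
  kd <- NA_real_
  kd_applied <- FALSE
  use_kd <- warm && cfg$lambda_kd > 0
  n_pix <- dim(x)[1L] * dim(x)[2L]
  tt <- if (cfg$student_temperature) cfg$temperature else 1
  s_soft <- temp_sigmoid(fw$logits, tt)
  if (use_kd) {
    if (cfg$sd_source == "per_sample_cache") {
      targets <- lapply(ids, function(id) sd_cache_get(cache, id, c(dim(x)[1:2])))
      have <- !vapply(targets, is.null, logical(1))
      if (any(have)) {
        kd_terms <- numeric(sum(have))
        j <- 0L
        for (i in which(have)) {
          s_i <- s_soft[, , 1L, i]
          diff <- s_i - targets[[i]]
          j <- j + 1L
          kd_terms[j] <- mean(diff^2)
          g[, , 1L, i] <- g[, , 1L, i] + cfg$lambda_kd *
            (2 * diff * s_i * (1 - s_i) / tt) / n_pix / sum(have)
        }
        kd <- mean(kd_terms)
        kd_applied <- TRUE
      }
    } else { # prev_batch
      prev <- cache$prev_batch
      if (!is.null(prev) && identical(dim(prev), dim(s_soft))) {
        diff <- s_soft - prev
        kd <- mean(diff^2)
        g <- g + cfg$lambda_kd * (2 * diff * s_soft * (1 - s_soft) / tt) /
          length(s_soft)
        kd_applied <- TRUE
      }
    }
  }
  total <- loss$total + if (kd_applied) cfg$lambda_kd * kd else 0
  components <- list(total = total, dice = loss$dice, bce = loss$bce,
                     kd = kd, kd_applied = kd_applied)
  check_finite_loss(components, ids)
  grads <- model_backward(model, params, fw$cache, g)
  upd <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
  # refresh the store with this step's (pre-update, detached) soft predictions
  if (cfg$sd_source == "per_sample_cache") {
    for (i in seq_along(ids)) {
      sd_cache_put(cache, ids[i], s_soft[, , 1L, i], epoch)
    }
  } else {
    cache$prev_batch <- s_soft
  }
  list(params = upd$params, opt = upd$opt, components = components)
}

#' One momentum-teacher (PRISM) training step
#'
#' The teacher's softened prediction supervises the student through the
#' distillation term whenever the epoch gate is open; the teacher forward pass
#' is a constant target (no gradient flows into teacher parameters). Strictly
#' ordered: student gradient step first, then the EMA update of the teacher
#' against the post-step student.
#'
#' @inheritParams train_step_base
#' @param teacher a `teacher_state` from [init_teacher()].
#' @param epoch current 1-based epoch, used by the distillation gate.
#' @return list with updated `params`, `opt`, `teacher`, loss `components`.
#' @export
train_step_prism <- function(model, params, opt, batch, cfg, teacher, epoch) {
  bad <- params_incompatibility(teacher$params, params)
  if (!is.null(bad)) stop("train_step_prism: teacher/student incompatible: ", bad)
  x <- stack_images(batch)
  y <- stack_masks(batch)
  kd_act <- distill_active(epoch, teacher) && cfg$lambda_kd > 0
  teacher_logits <- NULL
  if (kd_act) {
    teacher_logits <- model_forward(model, teacher$params, x)$logits
  }
  fw <- model_forward(model, params, x, keep_cache = TRUE)
  w <- loss_weights(cfg$lambda_kd, cfg$smooth_eps)
  loss <- total_loss(fw$logits, y, teacher_logits = teacher_logits,
                     temperature = cfg$temperature, weights = w,
                     kd_active = kd_act,
                     student_temperature = cfg$student_temperature,
                     with_grad = TRUE)
  check_finite_loss(loss, vapply(batch, `[[`, "", "id"))
  grads <- model_backward(model, params, fw$cache, loss$grad)
  upd <- adamw_step(params, grads, opt, cfg$learning_rate, cfg$weight_decay)
  if (cfg$ema_warmup == "always" || distill_active(epoch, teacher)) {
    teacher <- ema_update(teacher, upd$params)
  }
  list(params = upd$params, opt = upd$opt, teacher = teacher,
       components = loss[c("total", "dice", "bce", "kd", "kd_applied")])
}

# ---- SD cache --------------------------------------------------------------

#' Per-sample soft-prediction cache for the SD baseline
#'
#' @return an environment holding one soft map (and the epoch it was produced
#'   in) per sample id.
#' @export
sd_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$maps <- new.env(parent = emptyenv())
  e$prev_batch <- NULL
  e
}

sd_cache_put <- function(cache, id, soft_map, epoch) {
  assign(id, list(map = soft_map, epoch = epoch), envir = cache$maps)
  invisible(cache)
}

sd_cache_get <- function(cache, id, expected_dim) {
  if (!exists(id, envir = cache$maps, inherits = FALSE)) return(NULL)
  entry <- get(id, envir = cache$maps, inherits = FALSE)
  if (!identical(as.integer(dim(entry$map)), as.integer(expected_dim))) {
    warning(sprintf("sd cache: shape mismatch for '%s'; entry invalidated", id))
    rm(list = id, envir = cache$maps)
    return(NULL)
  }
  entry$map
}

# ---- fit -------------------------------------------------------------------

# supervised (Dice + BCE) validation loss, common scale across all modes
validation_loss <- function(model, params, val, cfg) {
  n <- length(val)
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + cfg$batch_size - 1L, n)
    x <- stack_images(val[i:j])
    y <- stack_masks(val[i:j])
    lg <- model_forward(model, params, x)$logits
    l <- total_loss(lg, y, weights = loss_weights(0, cfg$smooth_eps),
                    kd_active = FALSE)
    tot <- tot + l$total * (j - i + 1L)
    i <- j + 1L
  }
  tot / n
}

#' Train a model
#'
#' Runs `cfg$epochs` epochs in the configured mode, evaluating the supervised
#' validation loss after every epoch and retaining the parameters with the
#' lowest value seen (so checkpoint selection is on a common scale across
#' modes). Execution is deterministic given the config: shuffling, weight
#' initialization and the split all draw from named sub-seeds of `cfg$seed`.
#'
#' @param cfg a [train_config()].
#' @param train,val non-empty lists of segmentation samples.
#' @param model_factory function of `cfg` returning the model; defaults to the
#'   reference [seg_model()] sized by `cfg$base_width` and `cfg$levels`.
#' @return a `run_record` list: `history` (per-epoch loss components and
#'   validation loss), `steps` (per-step components and distillation-gate
#'   state), `best` (checkpointed params, epoch, val loss), `final_params`,
#'   `teacher` (prism mode), `model`, `config`.
#' @export
fit <- function(cfg, train, val, model_factory = NULL) {
  stopifnot(inherits(cfg, "train_config"), length(train) >= 1L,
            length(val) >= 1L)
  if (is.null(model_factory)) {
    model_factory <- function(cfg) {
      seg_model(in_channels = 3L, base_width = cfg$base_width,
                levels = cfg$levels)
    }
  }
  model <- model_factory(cfg)
  params <- init_params(model, cfg$seed)
  # fail fast if the model's output cannot match the masks
  probe <- model_forward(model, params, stack_images(train[1L]))$logits
  dmask <- dim(train[[1L]]$mask)
  if (!identical(dim(probe)[1:2], as.integer(dmask))) {
    stop(sprintf("fit: model output %s does not match mask size %s",
                 paste(dim(probe)[1:2], collapse = "x"),
                 paste(dmask, collapse = "x")))
  }
  opt <- adamw_init(params)
  teacher <- if (cfg$mode == "prism") {
    init_teacher(params, cfg$gamma, cfg$distill_start_epoch)
  } else {
    NULL
  }
  cache <- if (cfg$mode == "sd") sd_cache() else NULL

  n_train <- length(train)
  history <- vector("list", cfg$epochs)
  steps <- list()
  best <- list(params = NULL, epoch = NA_integer_, val_loss = Inf)

  for (epoch in seq_len(cfg$epochs)) {
    order <- with_local_seed(derive_seed(cfg$seed, "shuffle", epoch),
                             sample.int(n_train))
    comp_sums <- c(total = 0, dice = 0, bce = 0, kd = 0)
    kd_steps <- 0L
    n_steps <- 0L
    i <- 1L
    ep_steps <- list()
    while (i <= n_train) {
      j <- min(i + cfg$batch_size - 1L, n_train)
      batch <- train[order[i:j]]
      res <- switch(cfg$mode,
        base = train_step_base(model, params, opt, batch, cfg),
        sd = train_step_sd(model, params, opt, batch, cfg, cache,
                           warm = distill_active(epoch, cfg$distill_start_epoch),
                           epoch = epoch),
        prism = train_step_prism(model, params, opt, batch, cfg, teacher, epoch)
      )
      params <- res$params
      opt <- res$opt
      if (!is.null(res$teacher)) teacher <- res$teacher
      cm <- res$components
      n_steps <- n_steps + 1L
      comp_sums["total"] <- comp_sums["total"] + cm$total
      comp_sums["dice"] <- comp_sums["dice"] + cm$dice
      comp_sums["bce"] <- comp_sums["bce"] + cm$bce
      if (cm$kd_applied) {
        comp_sums["kd"] <- comp_sums["kd"] + cm$kd
        kd_steps <- kd_steps + 1L
      }
      ep_steps[[n_steps]] <- data.frame(
        epoch = epoch, step = n_steps, total = cm$total, dice = cm$dice,
        bce = cm$bce, kd = if (cm$kd_applied) cm$kd else NA_real_,
        kd_applied = cm$kd_applied
      )
      i <- j + 1L
    }
    val_loss <- validation_loss(model, params, val, cfg)
    if (val_loss < best$val_loss) {
      best <- list(params = lapply(params, function(a) a + 0),
                   epoch = epoch, val_loss = val_loss)
      class(best$params) <- class(params)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, total = comp_sums["total"] / n_steps,
      dice = comp_sums["dice"] / n_steps, bce = comp_sums["bce"] / n_steps,
      kd = if (kd_steps > 0) comp_sums["kd"] / kd_steps else NA_real_,
      kd_steps = kd_steps, n_steps = n_steps, val_loss = val_loss,
      row.names = NULL
    )
    steps <- c(steps, ep_steps)
  }
  structure(list(
    history = do.call(rbind, history),
    steps = do.call(rbind, steps),
    best = best,
    final_params = params,
    optimizer = opt,
    teacher = teacher,
    model = model,
    config = cfg
  ), class = "run_record")
}

#' Evaluate parameters on a sample set
#'
#' Predicts every sample, thresholds at `threshold`, and returns one
#' [compute_metrics()] row per sample.
#'
#' @param model a [seg_model()].
#' @param params parameter set (typically `run$best$params`).
#' @param samples list of segmentation samples.
#' @param threshold binarization threshold.
#' @return data frame of per-image metric records.
#' @export
evaluate_params <- function(model, params, samples, threshold = 0.5) {
  probs <- predict_prob(model, params, samples)
  do.call(rbind, lapply(seq_along(samples), function(i) {
    compute_metrics(binarize(probs[[i]], threshold), samples[[i]]$mask,
                    sample_id = samples[[i]]$id)
  }))
}
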