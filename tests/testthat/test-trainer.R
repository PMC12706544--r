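test_that("train config validates bounds and modes", {
  cfg <- train_config()
  expect_identical(cfg$mode, "base")
  expect_equal(cfg$learning_rate, 1e-4)
  expect_identical(cfg$batch_size, 4L)
  expect_identical(cfg$epochs, 30L)
  expect_equal(cfg$gamma, 0.90)
  expect_identical(cfg$distill_start_epoch, 7L)
  expect_equal(cfg$val_fraction, 0.10)
  expect_error(train_config(mode = "other"), "arg")
  expect_error(train_config(gamma = 1.2))
  expect_error(train_config(temperature = 0))
  expect_error(train_config(lambda_kd = -1))
})

test_that("the split is deterministic, disjoint, exhaustive and 90/10 by default", {
  ds <- tiny_phantoms(100, size = 16)
  sp <- split_dataset(ds, 0.10, seed = 5)
  expect_length(sp$train, 90)
  expect_length(sp$val, 10)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$val)), ids(ds))
  sp2 <- split_dataset(ds, 0.10, seed = 5)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_false(identical(ids(sp$train),
                         ids(split_dataset(ds, 0.10, seed = 6)$train)))
  sp10 <- split_dataset(ds[1:10], 0.10, seed = 1)
  expect_length(sp10$train, 9)
  expect_length(sp10$val, 1)
  expect_error(split_dataset(ds[1], 0.1, 1), "at least 2")
})

test_that("with the distillation weight at zero all three modes produce identical trajectories", {
  ds <- tiny_phantoms(12, size = 32, seed = 31)
  sp <- split_dataset(ds, 0.10, seed = 2)
  runs <- lapply(c("base", "sd", "prism"), function(mode) {
    cfg <- tiny_config(mode = mode, lambda_kd = 0, epochs = 2,
                       distill_start_epoch = 1)
    fit(cfg, sp$train, sp$val)
  })
  expect_identical(runs[[1]]$final_params, runs[[2]]$final_params)
  expect_identical(runs[[1]]$final_params, runs[[3]]$final_params)
  expect_identical(runs[[1]]$history$val_loss, runs[[3]]$history$val_loss)
})

test_that("identical config and seed reproduce the run bit-for-bit", {
  ds <- tiny_phantoms(10, size = 32, seed = 33)
  sp <- split_dataset(ds, 0.10, seed = 2)
  cfg <- tiny_config(mode = "prism", epochs = 2)
  r1 <- fit(cfg, sp$train, sp$val)
  r2 <- fit(cfg, sp$train, sp$val)
  expect_identical(r1$best$params, r2$best$params)
  expect_identical(r1$history, r2$history)
})

test_that("the checkpoint is the argmin of the per-epoch validation loss", {
  ds <- tiny_phantoms(10, size = 32, seed = 35)
  sp <- split_dataset(ds, 0.10, seed = 1)
  run <- fit(tiny_config(epochs = 4), sp$train, sp$val)
  expect_equal(run$best$val_loss, min(run$history$val_loss))
  expect_lte(run$best$val_loss, run$history$val_loss[4])
  expect_identical(run$best$epoch, which.min(run$history$val_loss))
  expect_identical(sum(run$history$n_steps[1]),
                   as.integer(ceiling(length(sp$train) / 4)))
})

test_that("the supervised loss decreases when overfitting one repeated batch", {
  ds <- tiny_phantoms(4, size = 32, seed = 37)
  cfg <- tiny_config(epochs = 50, learning_rate = 1e-3)
  run <- fit(cfg, ds, ds[1:2])
  expect_lt(mean(tail(run$history$total, 5)), run$history$total[1] * 0.5)
})

test_that("every mode can overfit a handful of phantoms to high training Dice", {
  # crisp-rim phantoms: the floor checks optimizer/model sanity, not the
  # irreducible ambiguity of a wide soft lesion boundary
  ds <- tiny_phantoms(8, size = 64, seed = 39, boundary_softness = 0.5)
  for (mode in c("base", "sd", "prism")) {
    cfg <- tiny_config(mode = mode, image_size = 64, epochs = 200,
                       batch_size = 2)
    run <- fit(cfg, ds, ds[1:2])
    rec <- evaluate_params(run$model, run$final_params, ds)
    expect_gte(mean(rec$dice), 0.95)
  }
})

test_that("SD consistency term is absent on the first pass and zero for an unchanged prediction", {
  ds <- tiny_phantoms(4, size = 32, seed = 41)
  cfg <- tiny_config(mode = "sd", distill_start_epoch = 1, learning_rate = 1e-300,
                     weight_decay = 0)
  m <- seg_model(3, cfg$base_width, cfg$levels)
  p <- init_params(m, cfg$seed)
  opt <- adamw_init_for_test(p)
  cache <- sd_cache()
  s1 <- train_step_sd(m, p, opt, ds, cfg, cache, warm = TRUE, epoch = 1)
  expect_false(s1$components$kd_applied)
  expect_equal(s1$components$total, s1$components$dice + s1$components$bce)
  # zero learning rate: the cached map equals the next prediction exactly
  s2 <- train_step_sd(m, s1$params, s1$opt, ds, cfg, cache, warm = TRUE,
                      epoch = 2)
  expect_true(s2$components$kd_applied)
  expect_identical(s2$components$kd, 0)
})

test_that("a prism step updates the student first and then the teacher", {
  ds <- tiny_phantoms(4, size = 32, seed = 43)
  cfg <- tiny_config(mode = "prism", distill_start_epoch = 1, gamma = 0.8)
  m <- seg_model(3, cfg$base_width, cfg$levels)
  p <- init_params(m, cfg$seed)
  opt <- adamw_init_for_test(p)
  teacher <- init_teacher(p, cfg$gamma, cfg$distill_start_epoch)
  pre_teacher <- teacher$params
  res <- train_step_prism(m, p, opt, ds, cfg, teacher, epoch = 1)
  # the stored teacher equals an EMA of the POST-step student
  for (k in names(p)) {
    expected <- 0.8 * pre_teacher[[k]] + 0.2 * res$params[[k]]
    expect_equal(res$teacher$params[[k]], expected, tolerance = 1e-14)
  }
  expect_true(res$components$kd_applied)
  # gamma = 0: the teacher tracks the student exactly
  cfg0 <- tiny_config(mode = "prism", distill_start_epoch = 1, gamma = 0)
  t0 <- init_teacher(p, 0, 1)
  r0 <- train_step_prism(m, p, opt, ds, cfg0, t0, epoch = 1)
  expect_identical(r0$teacher$params[names(p)], r0$params[names(p)])
})

test_that("the reference model learns the source task within ten epochs", {
  ds <- tiny_phantoms(200, size = 64, seed = 45)
  sp <- split_dataset(ds, 0.10, seed = 1)
  run <- fit(train_config(image_size = 64, epochs = 10, seed = 1),
             sp$train, sp$val)
  rec <- evaluate_params(run$model, run$best$params, sp$val)
  expect_gte(mean(rec$dice), 0.85)
})

test_that("a model whose output cannot match the masks is rejected before training", {
  ds <- tiny_phantoms(4, size = 32, seed = 47)
  ds[[1]]$mask <- ds[[1]]$mask[1:16, 1:16]
  expect_error(fit(tiny_config(), ds, ds), "does not match mask")
})
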