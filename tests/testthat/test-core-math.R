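test_that("sigmoid is correct, symmetric and overflow-safe", {
  expect_identical(sigmoid(0), 0.5)
  # high-precision reference value of 1 / (1 + exp(-1))
  expect_equal(sigmoid(1), 0.7310585786300049, tolerance = 1e-15)
  xs <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(xs) + sigmoid(-xs), rep(1, length(xs)), tolerance = 1e-15)
  big <- sigmoid(c(-500, 500, -750, 750))
  expect_true(all(is.finite(big)))
  expect_true(all(big >= 0 & big <= 1))
  expect_error(sigmoid(c(1, NaN)), "NaN")
})

test_that("temperature scaling softens towards 0.5 and is monotone", {
  temps <- c(0.5, 1, 2, 4)
  for (tt in temps) expect_identical(temp_sigmoid(0, tt), 0.5)
  # T = 1 is bit-identical to the plain sigmoid
  xs <- seq(-6, 6, by = 0.25)
  expect_identical(temp_sigmoid(xs, 1), sigmoid(xs))
  # sigma_T(2, T = 2) = sigma(1)
  expect_identical(temp_sigmoid(2, 2), sigmoid(1))
  for (tt in temps) {
    v <- temp_sigmoid(xs, tt)
    expect_true(all(diff(v) > 0)) # strictly increasing in x
  }
  # for x > 0 output decreases towards 0.5 as T grows; for x < 0 it increases
  for (x in c(0.5, 2, 5)) {
    v <- vapply(temps, function(tt) temp_sigmoid(x, tt), 0)
    expect_true(all(diff(v) < 0))
    v <- vapply(temps, function(tt) temp_sigmoid(-x, tt), 0)
    expect_true(all(diff(v) > 0))
  }
  expect_error(temp_sigmoid(1, 0), "positive")
  expect_error(temp_sigmoid(1, -2), "positive")
})

test_that("soft-Dice loss matches hand-computed values and stays in [0, 1]", {
  # perfect hard prediction: numerator and denominator coincide
  y <- array(c(1, 0, 0, 1), c(2, 2, 1, 1))
  expect_equal(dice_loss(y, y), 0)
  # all-zero prediction vs non-empty target: 1 up to the smoothing term
  z <- array(0, c(4, 4, 1, 1))
  y8 <- array(rep(c(1, 0), 8), c(4, 4, 1, 1))
  expect_equal(dice_loss(z, y8, smooth_eps = 1e-3), 1, tolerance = 1e-3)
  # 4x4 grid, constant 0.5 prediction, half-foreground target, eps = 1:
  # 1 - (2 * (0.5 * 8) + 1) / (0.5 * 16 + 8 + 1)
  p <- array(0.5, c(4, 4, 1, 1))
  expect_equal(dice_loss(p, y8, smooth_eps = 1), 1 - 9 / 17, tolerance = 1e-15)
  # range on random inputs
  set.seed(1)
  for (i in 1:20) {
    pr <- array(runif(32), c(4, 8, 1, 1))
    tg <- array(rbinom(32, 1, 0.4), c(4, 8, 1, 1))
    d <- dice_loss(pr, tg)
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(dice_loss(array(0, c(2, 2, 1, 1)), array(0, c(3, 3, 1, 1))),
               "shape")
})

test_that("BCE loss matches closed-form values and clamps extremes", {
  y <- array(rbinom(64, 1, 0.5), c(8, 8, 1, 1))
  p <- array(0.5, c(8, 8, 1, 1))
  expect_equal(bce_loss(p, y), log(2), tolerance = 1e-12)
  # -log(sigmoid(1)) on a single foreground pixel
  expect_equal(bce_loss(array(0.7310585786300049, c(1, 1, 1, 1)),
                        array(1, c(1, 1, 1, 1))),
               0.3132616875182228, tolerance = 1e-12)
  # exact 0/1 predictions are clamped, not rejected, and near-perfect
  # predictions approach zero loss
  expect_lt(bce_loss(y, y), 1e-5)
  expect_gt(bce_loss(y, y), 0)
})

test_that("distillation MSE is zero iff identical and bounded by 1", {
  s <- array(runif(32), c(4, 8, 1, 1))
  expect_identical(kd_loss(s, s), 0)
  ones <- array(1, c(4, 4, 1, 1))
  zeros <- array(0, c(4, 4, 1, 1))
  expect_equal(kd_loss(ones, zeros), 1)
  expect_equal(kd_loss(array(0.75, c(2, 2, 1, 1)), array(0.25, c(2, 2, 1, 1))),
               0.25, tolerance = 1e-15)
})

test_that("total loss with distillation disabled equals the supervised loss in value and gradient", {
  set.seed(7)
  for (i in 1:100) {
    z <- array(rnorm(16, sd = 2), c(4, 4, 1, 1))
    zt <- array(rnorm(16, sd = 2), c(4, 4, 1, 1))
    y <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
    a <- total_loss(z, y, teacher_logits = zt, kd_active = FALSE,
                    weights = loss_weights(1), with_grad = TRUE)
    b <- total_loss(z, y, teacher_logits = zt, kd_active = TRUE,
                    weights = loss_weights(0), with_grad = TRUE)
    expect_identical(a$total, b$total)
    expect_identical(a$grad, b$grad)
  }
  expect_error(total_loss(array(0, c(2, 2, 1, 1)), array(0, c(2, 2, 1, 1)),
                          kd_active = TRUE),
               "teacher")
})

test_that("composite loss on a fixed 2x2 example equals the hand-summed terms", {
  z <- array(c(1.2, -0.4, 0.3, 2.0), c(2, 2, 1, 1))
  zt <- array(c(0.8, -1.0, 0.5, 1.5), c(2, 2, 1, 1))
  y <- array(c(1, 0, 0, 1), c(2, 2, 1, 1))
  Tt <- 2; lam <- 1; eps <- 1
  # independent evaluation with explicit arithmetic
  p <- 1 / (1 + exp(-z))
  dice_ref <- 1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
  bce_ref <- -mean(y * log(p) + (1 - y) * log(1 - p))
  ss <- 1 / (1 + exp(-z / Tt))
  ts <- 1 / (1 + exp(-zt / Tt))
  kd_ref <- mean((ss - ts)^2)
  got <- total_loss(z, y, teacher_logits = zt, temperature = Tt,
                    weights = loss_weights(lam, eps), kd_active = TRUE)
  expect_equal(got$dice, dice_ref, tolerance = 1e-14)
  expect_equal(got$bce, bce_ref, tolerance = 1e-14)
  expect_equal(got$kd, kd_ref, tolerance = 1e-14)
  expect_equal(got$total, dice_ref + bce_ref + lam * kd_ref, tolerance = 1e-14)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(11)
  z <- array(rnorm(18), c(3, 3, 1, 2))
  zt <- array(rnorm(18), c(3, 3, 1, 2))
  y <- array(rbinom(18, 1, 0.5), c(3, 3, 1, 2))
  w <- loss_weights(0.7, 1)
  g <- total_loss(z, y, zt, temperature = 2, weights = w, kd_active = TRUE,
                  with_grad = TRUE)$grad
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    num <- (total_loss(zp, y, zt, temperature = 2, weights = w,
                       kd_active = TRUE)$total -
            total_loss(zm, y, zt, temperature = 2, weights = w,
                       kd_active = TRUE)$total) / 2e-6
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("losses are invariant to a simultaneous pixel permutation", {
  set.seed(5)
  z <- array(rnorm(64), c(8, 8, 1, 1))
  y <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  zt <- array(rnorm(64), c(8, 8, 1, 1))
  perm <- sample(64)
  zp <- array(z[perm], dim(z)); yp <- array(y[perm], dim(y))
  ztp <- array(zt[perm], dim(zt))
  a <- total_loss(z, y, zt, kd_active = TRUE)
  b <- total_loss(zp, yp, ztp, kd_active = TRUE)
  expect_equal(a$total, b$total, tolerance = 1e-14)
  expect_equal(dice_loss(sigmoid(z), y), dice_loss(sigmoid(zp), yp),
               tolerance = 1e-14)
  expect_equal(bce_loss(sigmoid(z), y), bce_loss(sigmoid(zp), yp),
               tolerance = 1e-14)
})
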