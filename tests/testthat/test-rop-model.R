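test_that("weighted BCE matches hand arithmetic and reduces to BCE at w_pos 1", {
  expect_equal(weighted_bce(0.8, 1, w_pos = 2), -2 * log(0.8), tolerance = 1e-12)
  expect_equal(round(weighted_bce(0.8, 1, w_pos = 2), 4), 0.4463)
  expect_equal(weighted_bce(0.5, 0, w_pos = 5), log(2), tolerance = 1e-12)
  expect_lt(weighted_bce(1 - 1e-13, 1, w_pos = 7), 1e-10)

  p <- seq(0.05, 0.95, by = 0.05)
  for (y in c(0, 1)) {
    std <- -(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(weighted_bce(p, y, 1), std, tolerance = 1e-12)
  }
  # the weight scales only the positive term, proportionally
  expect_equal(weighted_bce(0.3, 1, 4) / weighted_bce(0.3, 1, 1), 4,
               tolerance = 1e-12)
  expect_equal(weighted_bce(0.3, 0, 4), weighted_bce(0.3, 0, 1),
               tolerance = 1e-12)
  expect_error(weighted_bce(NaN, 1), "NaN")
  expect_error(weighted_bce(0.5, 1, w_pos = 0.5), "w_pos")
})

test_that("augmentation is identity when off, involutive for flips, exact for rotation", {
  crop <- array(runif(64 * 64 * 3), c(64, 64, 3))
  off <- augmentation_spec(rotation_max_degrees = 0, horizontal_flip = FALSE,
                           vertical_flip = FALSE,
                           jitter = c(brightness = 0, contrast = 0,
                                      saturation = 0))
  expect_identical(augment(crop, off, seed = 1), crop)

  hflip <- augmentation_spec(rotation_max_degrees = 0,
                             horizontal_flip = TRUE, vertical_flip = FALSE,
                             jitter = c(brightness = 0, contrast = 0,
                                        saturation = 0))
  # find a seed for which the flip fires, then apply twice
  seed <- which(vapply(1:20, function(s) {
    !identical(augment(crop, hflip, seed = s), crop)
  }, logical(1)))[1]
  once <- augment(crop, hflip, seed = seed)
  expect_identical(augment(once, hflip, seed = seed), crop)

  # +90 degrees moves a center offset (dx, dy) to (-dy, dx):
  # the bright pixel at (x=10, y=20) of a 64x64 crop lands at (43, 10)
  img <- matrix(0, 64, 64)
  img[20 + 1, 10 + 1] <- 1
  rot <- rotate_image(img, 90)
  expect_equal(dim(rot), c(64, 64))
  expect_equal(rot[10 + 1, 43 + 1], 1, tolerance = 1e-9)
  expect_equal(sum(rot), 1, tolerance = 1e-9)

  full <- augmentation_spec()
  a1 <- augment(crop, full, seed = 7)
  expect_identical(a1, augment(crop, full, seed = 7))
  expect_identical(dim(a1), dim(crop))
  expect_error(augmentation_spec(rotation_max_degrees = 200), "rotation")
})

test_that("ROP training is deterministic, leakage-checked and separates the classes", {
  fx <- rop_fixture()
  expect_gte(fx$model$val_auroc, 0.85)
  again <- train_rop_classifier(rop_subset(fx$ds, fx$train),
                                rop_subset(fx$ds, fx$val),
                                rop_train_config(seed = 5))
  expect_identical(again$net$val_loss, fx$model$net$val_loss)
  expect_gt(nrow(fx$model$net$log), 0)
  expect_true(all(c("train_loss", "val_loss") %in% names(fx$model$net$log)))

  leaky_val <- rop_subset(fx$ds, c(fx$val, fx$train[1]))
  expect_error(train_rop_classifier(rop_subset(fx$ds, fx$train), leaky_val,
                                    rop_train_config(seed = 5)),
               class = "patient_leakage")
  expect_error(train_rop_classifier(
    list(crops = fx$ds$crops[1:4], labels = rep(1L, 4)),
    rop_subset(fx$ds, fx$val), rop_train_config(seed = 5)), "both classes")
})

test_that("temperature fitting recovers generative calibration and its optimality", {
  set.seed(42)
  p <- runif(5000, 0.02, 0.98)
  z <- log(p / (1 - p))
  y <- rbinom(5000, 1, p)

  t_cal <- fit_temperature(z, y)
  expect_gte(t_cal$T, 0.9); expect_lte(t_cal$T, 1.1)

  t_dbl <- fit_temperature(2 * z, y)
  expect_gte(t_dbl$T, 1.8); expect_lte(t_dbl$T, 2.2)

  expect_lte(t_cal$nll, t_cal$nll_t1 + 1e-12)
  expect_error(fit_temperature(z, rep(1, 5000)), "both classes")
})

test_that("temperature application is monotone, rank-preserving and validated", {
  expect_equal(apply_temperature(0, 3.7), 0.5)
  expect_equal(apply_temperature(log(3), 1), 0.75, tolerance = 1e-12)
  z <- c(-2, -0.3, 0.1, 1.4, 3)
  pT <- apply_temperature(z, 2.5)
  expect_true(all(diff(pT) > 0))
  set.seed(8)
  zz <- rnorm(400); yy <- rbinom(400, 1, 0.4)
  expect_equal(auroc(apply_temperature(zz, 3.3), yy), auroc(zz, yy),
               tolerance = 1e-12)
  expect_error(apply_temperature(1, -2), "positive")
  expect_error(apply_temperature(1, 0), "positive")
})

test_that("calibration does not worsen NLL or expected calibration error", {
  set.seed(5)
  p <- runif(4000, 0.05, 0.95)
  y <- rbinom(4000, 1, p)
  z_over <- 3 * log(p / (1 - p))  # overconfident logits
  half <- seq_len(2000)
  tfit <- fit_temperature(z_over[half], y[half])
  held_z <- z_over[-half]; held_y <- y[-half]
  nll <- function(prob) mean(weighted_bce(prob, held_y, 1))
  expect_lte(nll(apply_temperature(held_z, tfit)), nll(sigmoid_ref(held_z)))
  expect_lte(ece10(apply_temperature(held_z, tfit), held_y),
             ece10(sigmoid_ref(held_z), held_y))
})

test_that("a calibrated model is closer to T-neutral than the raw net on validation", {
  fx <- rop_fixture()
  expect_false(is.null(fx$model$temperature))
  expect_gt(fx$model$temperature$T, 0)
  expect_lte(fx$model$temperature$nll, fx$model$temperature$nll_t1 + 1e-12)
  pr <- predict(fx$model, fx$ds$crops[fx$val], type = "prob")
  zz <- predict(fx$model, fx$ds$crops[fx$val], type = "logit")
  expect_equal(auroc(pr, fx$ds$labels[fx$val]),
               auroc(zz, fx$ds$labels[fx$val]), tolerance = 1e-12)
})
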