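# Small synthetic regression sets exercising the real training loop: the
# label is the amplitude of a fixed template mixed into uniform noise, so a
# noiseless linear readout exists and labels span [0, 1].
toy_dataset <- function(n, seed, H = 32L, W = 16L) {
  set.seed(seed)
  template <- runif(H * W)
  amp <- seq(0, 1, length.out = n)
  x <- 0.5 * matrix(runif(H * W * n), H * W, n) +
    0.5 * template %o% amp
  list(x = x, y = amp, height_px = H, width_px = W)
}

toy_config <- function(...) {
  train_config("desk", height_px = 32L, width_px = 16L,
               conv_channels = c(2L, 4L), dense_width = 8L,
               n_repetitions = 2L, ...)
}

test_that("training is deterministic given (data, config, seed)", {
  tr <- toy_dataset(30, 1); va <- toy_dataset(10, 2)
  cfg <- toy_config(epochs = 4L)
  s1 <- train_session(tr, va, cfg, seed = 3)
  s2 <- train_session(tr, va, cfg, seed = 3)
  expect_identical(s1$train_mse, s2$train_mse)
  expect_identical(s1$val_mse, s2$val_mse)
  expect_identical(s1$model$weights, s2$model$weights)
  s3 <- train_session(tr, va, cfg, seed = 4)
  expect_false(identical(s1$val_mse, s3$val_mse))
})

test_that("session-best selection attains the validation-loss minimum", {
  tr <- toy_dataset(40, 5); va <- toy_dataset(15, 6)
  s <- train_session(tr, va, toy_config(epochs = 12L), seed = 1)
  expect_equal(s$best_val_mse, min(s$val_mse))
  expect_equal(s$val_mse[s$best_epoch], min(s$val_mse))
  # the returned weights reproduce the recorded best loss (float training,
  # double re-evaluation)
  p <- predict_model(s$model, va$x)
  expect_equal(mean((p - va$y)^2), s$best_val_mse, tolerance = 1e-2)
})

test_that("a memorizable set is overfit to near-zero training error", {
  tr <- toy_dataset(10, 7)
  s <- train_session(tr, tr, toy_config(epochs = 200L, learning_rate = 1e-2),
                     seed = 2)
  p <- predict_model(s$model, tr$x)
  expect_lt(sqrt(mean((p - tr$y)^2)), 0.05)
})

test_that("constant labels drive validation MSE toward zero", {
  tr <- toy_dataset(20, 8); tr$y <- rep(0.4, 20)
  va <- toy_dataset(8, 9); va$y <- rep(0.4, 8)
  short <- train_session(tr, va, toy_config(epochs = 10L), seed = 1)
  long <- train_session(tr, va, toy_config(epochs = 200L), seed = 1)
  expect_lt(long$best_val_mse, short$best_val_mse)
  expect_lt(long$best_val_mse, 0.01)  # (0.4)^2 = 0.16 at initialization
})

test_that("empty splits and shared patients are rejected", {
  tr <- toy_dataset(10, 1)
  expect_error(train_session(tr, list(x = tr$x[, 0], y = numeric(0)),
                             toy_config()),
               class = "ritmap_data_error")
  tr$manifest <- data.frame(patient_id = rep("A", 10))
  va <- toy_dataset(5, 2)
  va$manifest <- data.frame(patient_id = c("A", "B", "B", "B", "B"))
  expect_error(train_session(tr, va, toy_config()),
               class = "ritmap_data_error")
})

test_that("repetitions build seeded ensembles of session-best models", {
  tr <- toy_dataset(25, 3); va <- toy_dataset(10, 4)
  cfg <- toy_config(epochs = 3L, n_repetitions = 3L, base_seed = 50L)
  ens <- run_repetitions(tr, va, cfg, eccentricity_mm = 0.25)
  expect_length(ens$models, 3L)
  expect_equal(ens$eccentricity_mm, 0.25)
  expect_equal(vapply(ens$sessions, `[[`, integer(1), "seed"), 50:52)
  # one repetition: ensemble prediction equals the single model's
  cfg1 <- toy_config(epochs = 3L, n_repetitions = 1L, base_seed = 50L)
  ens1 <- run_repetitions(tr, va, cfg1)
  expect_equal(predict_rit(ens1, va$x),
               predict_rit(ens1$models[[1]], va$x))
  # sessions are independent of ordering: same seed -> same session result
  expect_identical(ens$sessions[[1]]$model$weights, ens1$models[[1]]$weights)
})

test_that("training profiles carry the published protocol", {
  pf <- train_config("paper_faithful")
  expect_equal(pf$learning_rate, 2e-4)
  expect_equal(pf$batch_size, 26L)
  expect_equal(pf$epochs, 600L)
  expect_equal(pf$n_repetitions, 9L)
  expect_equal(pf$optimizer, "nadam")
  expect_equal(pf$loss, "mse")
  expect_equal(pf$init, "xavier_normal")
  dk <- train_config("desk")
  expect_equal(dk$batch_size, 26L)   # protocol constants survive scaling
  expect_equal(dk$optimizer, "nadam")
  expect_error(train_config("desk", nonsense = 1),
               class = "ritmap_config_error")
  expect_error(train_config("desk", learning_rate = 0),
               class = "ritmap_config_error")
})

test_that("loss logs round-trip through CSV", {
  tr <- toy_dataset(12, 1); va <- toy_dataset(6, 2)
  s <- train_session(tr, va, toy_config(epochs = 3L), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_loss_log(s, path)
  log <- read.csv(path)
  expect_equal(log$epoch, 1:3)
  expect_equal(log$val_mse, s$val_mse)
})
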