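# Pure-R reference forward pass: direct convolution loops, independent of
# the C++ im2col/GEMM implementation and of its memory layout tricks.
r_forward_reference <- function(model, patch) {
  arch <- model$arch
  A <- list(patch)
  for (li in seq_along(arch$conv_channels)) {
    Wm <- model$weights[[2 * li - 1]]
    bv <- model$weights[[2 * li]]
    Cin <- length(A)
    Hi <- nrow(A[[1]]); Wi <- ncol(A[[1]])
    Ho <- (Hi - 1) %/% 2 + 1; Wo <- (Wi - 1) %/% 2 + 1
    out <- vector("list", nrow(Wm))
    for (co in seq_len(nrow(Wm))) {
      Z <- matrix(bv[co, 1], Ho, Wo)
      for (ci in seq_len(Cin)) for (kw in 0:2) for (kh in 0:2) {
        wgt <- Wm[co, (kw * 3 + kh) * Cin + ci]
        for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
          h <- 2 * ho - 2 + kh   # 1-based: 2*(ho-1) - 1 + kh + 1
          w <- 2 * wo - 2 + kw
          if (h >= 1 && h <= Hi && w >= 1 && w <= Wi) {
            Z[ho, wo] <- Z[ho, wo] + wgt * A[[ci]][h, w]
          }
        }
      }
      out[[co]] <- pmax(Z, 0)
    }
    A <- out
  }
  feats <- if (identical(arch$pooling, "flatten")) {
    as.numeric(do.call(rbind, lapply(A, function(m) as.numeric(m))))
  } else {
    vapply(A, mean, numeric(1))
  }
  nw <- length(model$weights)
  d1 <- pmax(model$weights[[nw - 3]] %*% feats + model$weights[[nw - 2]], 0)
  as.numeric(model$weights[[nw - 1]] %*% d1 + model$weights[[nw]])
}

test_that("C++ forward matches an independent pure-R convolution oracle", {
  for (pooling in c("flatten", "gap")) {
    arch <- cnn_architecture(16L, 8L, conv_channels = c(2L, 3L),
                             dense_width = 4L, pooling = pooling)
    model <- build_model(arch, seed = 42)
    set.seed(9)
    for (i in 1:3) {
      patch <- matrix(runif(16 * 8), 16, 8)
      expect_equal(predict_model(model, patch),
                   r_forward_reference(model, patch),
                   tolerance = 1e-10,
                   label = paste("pooling", pooling, "draw", i))
    }
  }
})

test_that("model building is seeded and outputs one finite scalar", {
  arch <- cnn_architecture(32L, 16L, c(2L, 2L), 4L)
  m1 <- build_model(arch, seed = 7)
  m2 <- build_model(arch, seed = 7)
  m3 <- build_model(arch, seed = 8)
  patch <- matrix(runif(32 * 16), 32, 16)
  expect_identical(predict_model(m1, patch), predict_model(m2, patch))
  expect_false(identical(predict_model(m1, patch), predict_model(m3, patch)))
  out <- predict_model(m1, patch)
  expect_length(out, 1L)
  expect_true(is.finite(out))
  expect_error(predict_model(m1, matrix(0, 8, 8)),
               class = "ritmap_shape_error")
})

test_that("default architectures stay under one million parameters", {
  for (p in c("desk", "paper_faithful")) {
    m <- build_model(ritmap:::arch_from_config(train_config(p)), seed = 1)
    expect_lte(n_params(m), 1e6)
  }
})

test_that("Xavier-normal init has the prescribed spread", {
  arch <- cnn_architecture(64L, 32L, c(8L, 8L), 16L)
  m <- build_model(arch, seed = 3)
  w2 <- m$weights[[3]]  # conv2: 8 x 72, fan_in 72, fan_out 72
  expect_equal(sd(w2), sqrt(2 / (72 + 72)), tolerance = 0.15)
  expect_equal(mean(w2), 0, tolerance = 0.02)
  # biases start at zero
  expect_true(all(m$weights[[2]] == 0))
})

test_that("ensemble prediction is 40x the mean normalized output", {
  arch <- cnn_architecture(16L, 8L, c(2L), 4L)
  patch <- matrix(runif(16 * 8), 16, 8)
  m025 <- constant_model(arch, 0.25)
  expect_equal(predict_rit(m025, patch), 10.0)
  ens <- model_ensemble(list(constant_model(arch, 0.2),
                             constant_model(arch, 0.4)))
  expect_equal(predict_rit(ens, patch), 12.0)
  expect_equal(predict_rit(constant_model(arch, 0), patch), 0.0)
  # averaging commutes with the 40x scaling; no hidden clipping
  mneg <- constant_model(arch, -0.1)
  expect_equal(predict_rit(mneg, patch), -4.0)
  ens2 <- model_ensemble(list(m025, mneg))
  expect_equal(predict_rit(ens2, patch),
               mean(c(predict_rit(m025, patch), predict_rit(mneg, patch))))
  # mixed architectures are rejected
  expect_error(model_ensemble(list(m025,
                                   constant_model(cnn_architecture(16L, 8L,
                                                                   c(3L), 4L),
                                                  0.1))),
               class = "ritmap_shape_error")
})

test_that("evaluate matches closed forms and flags degenerate truth", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0); expect_equal(m$mae, 0); expect_equal(m$pearson, 1)
  expect_warning(m2 <- evaluate(c(0, 0), c(3, 4)), "constant")
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$mae, 3.5)
  expect_true(is.na(m2$pearson))
  truth <- c(2, 5, 9, 11)
  expect_equal(evaluate(2 * truth + 1, truth)$pearson, 1.0)
  expect_warning(mc <- evaluate(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(mc$pearson))
  expect_error(evaluate(1:3, 1:4), class = "ritmap_data_error")
})
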