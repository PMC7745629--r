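#' CNN architecture descriptor
#'
#' Stride-2 3x3 convolution blocks (zero padding 1, ReLU), one per entry of
#' `conv_channels`, followed by global average pooling, a ReLU dense layer
#' and a single linear output node. The linear head predicts RIT / 40, the
#' normalized label.
#'
#' @param height_px,width_px input window dimensions.
#' @param conv_channels integer vector of output channels per conv block.
#' @param dense_width width of the penultimate dense layer.
#' @param pooling `"flatten"` feeds the whole final feature map to the dense
#'   layer (keeps the spatial alignment the anatomically restricted window
#'   provides); `"gap"` global-average-pools it first.
#' @return list of class `cnn_architecture`.
#' @export
cnn_architecture <- function(height_px = 256L, width_px = 64L,
                             conv_channels = c(16L, 32L, 64L, 64L),
                             dense_width = 32L,
                             pooling = c("flatten", "gap")) {
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 conv_channels = as.integer(conv_channels),
                 dense_width = as.integer(dense_width),
                 pooling = match.arg(pooling)),
            class = "cnn_architecture")
}

# spatial size after the stride-2 conv stack
conv_out_dims <- function(arch) {
  h <- arch$height_px; w <- arch$width_px
  for (i in seq_along(arch$conv_channels)) {
    h <- (h - 1L) %/% 2L + 1L
    w <- (w - 1L) %/% 2L + 1L
  }
  c(h, w)
}

# Xavier (Glorot) normal draw for a fan_out x fan_in matrix.
xavier_normal <- function(n_out, n_in, fan_in, fan_out) {
  matrix(rnorm(n_out * n_in, 0, sqrt(2 / (fan_in + fan_out))), n_out, n_in)
}

#' Build a CNN model with Xavier-normal initial weights
#'
#' Convolutional and dense weights are drawn from the Xavier (Glorot) normal
#' distribution seeded by `seed`; biases start at zero. Two builds with the
#' same seed produce identical initial predictions.
#'
#' @param arch a [cnn_architecture()].
#' @param seed RNG seed for the initialization.
#' @return object of class `rit_cnn` (architecture + weight list).
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  set.seed(seed)
  weights <- list()
  cin <- 1L
  for (cout in arch$conv_channels) {
    # conv fan counts use the full 3x3 receptive field
    weights[[length(weights) + 1L]] <-
      xavier_normal(cout, 9L * cin, fan_in = 9L * cin, fan_out = 9L * cout)
    weights[[length(weights) + 1L]] <- matrix(0, cout, 1)
    cin <- cout
  }
  c_last <- arch$conv_channels[length(arch$conv_channels)]
  n_feat <- if (identical(arch$pooling, "flatten")) {
    c_last * prod(conv_out_dims(arch))
  } else {
    c_last
  }
  weights[[length(weights) + 1L]] <-
    xavier_normal(arch$dense_width, n_feat, n_feat, arch$dense_width)
  weights[[length(weights) + 1L]] <- matrix(0, arch$dense_width, 1)
  weights[[length(weights) + 1L]] <-
    xavier_normal(1L, arch$dense_width, arch$dense_width, 1L)
  weights[[length(weights) + 1L]] <- matrix(0, 1, 1)
  structure(list(arch = arch, weights = weights, seed = as.integer(seed)),
            class = "rit_cnn")
}

#' Number of trainable parameters
#' @param model a `rit_cnn`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

# Coerce a patch / list of patches / pixel matrix into the flat
# (pixels x n) layout, checking the shape against the architecture.
as_input_matrix <- function(x, arch) {
  npix <- arch$height_px * arch$width_px
  if (inherits(x, "training_window")) x <- x$patch
  if (is.list(x)) {
    x <- vapply(x, function(p) {
      if (inherits(p, "training_window")) p <- p$patch
      as.numeric(p)
    }, numeric(npix))
  }
  if (is.matrix(x) && nrow(x) == arch$height_px && ncol(x) == arch$width_px) {
    x <- matrix(as.numeric(x), ncol = 1)
  }
  if (!is.matrix(x) || nrow(x) != npix) {
    rit_stop("ritmap_shape_error",
             "input shape mismatch: model expects %d x %d patches",
             arch$height_px, arch$width_px)
  }
  x
}

#' Normalized model output
#'
#' Raw linear-head output (predicted RIT / 40) for one or more patches.
#'
#' @param model a `rit_cnn`.
#' @param x a `training_window`, a height x width patch matrix in \[0, 1\],
#'   a flat pixels-by-n matrix, or a list of patches.
#' @return numeric vector of unbounded normalized predictions.
#' @export
predict_model <- function(model, x) {
  x <- as_input_matrix(x, model$arch)
  as.numeric(cpp_forward(model$weights, unclass(model$arch), x))
}

#' Model ensemble for one anatomic location
#'
#' @param models list of `rit_cnn` with identical architectures.
#' @param eccentricity_mm the location the ensemble was trained at.
#' @param sessions optional list of session results the members came from.
#' @return object of class `rit_ensemble`.
#' @export
model_ensemble <- function(models, eccentricity_mm = NA_real_,
                           sessions = NULL) {
  stopifnot(length(models) >= 1L)
  a0 <- models[[1]]$arch
  same <- vapply(models, function(m) identical(unclass(m$arch), unclass(a0)),
                 logical(1))
  if (!all(same)) {
    rit_stop("ritmap_shape_error", "ensemble members must share one architecture")
  }
  structure(list(models = models, eccentricity_mm = eccentricity_mm,
                 sessions = sessions), class = "rit_ensemble")
}

#' Ensemble RIT prediction in minutes
#'
#' `40 x` the across-member mean of the normalized linear-head outputs. No
#' clipping is applied, so predictions scale exactly with the head output.
#'
#' @param ensemble a [model_ensemble()] (a single `rit_cnn` is promoted to a
#'   one-member ensemble).
#' @param x patches as in [predict_model()].
#' @return predicted RIT in minutes (vector over patches).
#' @export
predict_rit <- function(ensemble, x) {
  if (inherits(ensemble, "rit_cnn")) ensemble <- model_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "rit_ensemble"))
  x <- as_input_matrix(x, ensemble$models[[1]]$arch)
  member_out <- vapply(ensemble$models, function(m) {
    as.numeric(cpp_forward(m$weights, unclass(m$arch), x))
  }, numeric(ncol(x)))
  member_out <- matrix(member_out, nrow = ncol(x))
  40 * rowMeans(member_out)
}

#' Regression metrics in minutes
#'
#' Root mean squared error, mean absolute error and Pearson correlation
#' between predicted and true RIT.
#'
#' @param preds,truth numeric vectors in minutes, equal length.
#' @return list with `rmse`, `mae`, `pearson`.
#' @export
evaluate <- function(preds, truth) {
  if (length(preds) != length(truth) || length(preds) == 0L) {
    rit_stop("ritmap_data_error", "preds and truth must have equal nonzero length")
  }
  r <- preds - truth
  pearson <- if (sd(truth) == 0 || sd(preds) == 0) {
    warning("constant predictions or truth; Pearson correlation undefined")
    NA_real_
  } else {
    cor(preds, truth)
  }
  list(rmse = sqrt(mean(r^2)), mae = mean(abs(r)), pearson = pearson)
}
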