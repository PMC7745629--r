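#' Training configuration and profiles
#'
#' The `paper_faithful` profile reproduces the published training protocol:
#' Nesterov-Adam (Nadam) at an initial learning rate of 2e-4, batch size 26,
#' 600 epochs, MSE loss on RIT/40 against inputs/255, Xavier-normal
#' initialization, nine training repetitions per location with per-session
#' best-validation-epoch weight selection.
#'
#' The `desk` profile keeps the optimizer, loss, normalizations, batch size
#' and selection rule but scales the schedule to a single CPU: 30 epochs,
#' 3 repetitions, a smaller conv stack, and a learning rate of 5e-3. The
#' higher rate compensates for the ~100x fewer optimizer steps a desk-scale
#' run takes (Adam-family steps have magnitude ~lr, so total parameter
#' displacement scales with lr x steps); at 2e-4 a 30-epoch run cannot move
#' the head from its near-zero initialization to the label mean.
#'
#' @param profile `"desk"` or `"paper_faithful"`.
#' @param ... overrides for any field (e.g. `epochs`, `learning_rate`,
#'   `conv_channels`, `base_seed`).
#' @return list of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper_faithful"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    learning_rate = 2e-4,
    batch_size = 26L,
    epochs = 600L,
    n_repetitions = 9L,
    optimizer = "nadam",
    loss = "mse",
    init = "xavier_normal",
    input_scale = 255,
    label_scale_minutes = 40,
    beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
    conv_channels = c(16L, 32L, 64L, 64L),
    dense_width = 32L,
    pooling = "flatten",
    height_px = 256L, width_px = 64L,
    base_seed = 100L
  )
  if (profile == "desk") {
    cfg$learning_rate <- 5e-3
    cfg$epochs <- 30L
    cfg$n_repetitions <- 3L
    cfg$conv_channels <- c(4L, 8L, 16L, 16L)
    cfg$dense_width <- 16L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    rit_stop("ritmap_config_error", "unknown train_config fields: %s",
             paste(bad, collapse = ", "))
  }
  cfg[names(over)] <- over
  if (cfg$learning_rate <= 0 || cfg$batch_size < 1L || cfg$n_repetitions < 1L) {
    rit_stop("ritmap_config_error",
             "need learning_rate > 0, batch_size >= 1, n_repetitions >= 1")
  }
  class(cfg) <- "train_config"
  cfg
}

arch_from_config <- function(cfg) {
  cnn_architecture(cfg$height_px, cfg$width_px, cfg$conv_channels,
                   cfg$dense_width, pooling = cfg$pooling)
}

check_patient_disjoint <- function(train, val) {
  if (!is.null(train$manifest) && !is.null(val$manifest)) {
    both <- intersect(unique(train$manifest$patient_id),
                      unique(val$manifest$patient_id))
    if (length(both)) {
      rit_stop("ritmap_data_error",
               "train/val share patients: %s", paste(both, collapse = ", "))
    }
  }
}

#' Run one training session
#'
#' Minimizes MSE between the linear head and the normalized label (RIT/40)
#' with Nadam, recording per-epoch train/validation loss, and returns the
#' weights of the epoch with the lowest validation loss. Sample order is
#' reshuffled every epoch from the session seed; the last incomplete batch
#' is kept. Deterministic given `(data, cfg, seed)` on a single thread.
#'
#' @param train,val window datasets from [build_window_dataset()] (or any
#'   list with `x` pixels-by-n in \[0, 1\] and `y` normalized labels).
#' @param cfg a [train_config()].
#' @param seed session seed (weights init + shuffling).
#' @return object of class `rit_session`: `model` (best-epoch `rit_cnn`),
#'   `train_mse`, `val_mse`, `best_epoch`, `seed`.
#' @export
train_session <- function(train, val, cfg, seed = cfg$base_seed) {
  if (is.null(train$x) || ncol(train$x) == 0L ||
      is.null(val$x) || ncol(val$x) == 0L) {
    rit_stop("ritmap_data_error", "empty training or validation split")
  }
  check_patient_disjoint(train, val)
  arch <- arch_from_config(cfg)
  model <- build_model(arch, seed = seed)   # also seeds the epoch shuffles
  fit <- cpp_train(model$weights, unclass(arch), train$x, train$y,
                   val$x, val$y, lr = cfg$learning_rate,
                   batch_size = as.integer(cfg$batch_size),
                   epochs = as.integer(cfg$epochs),
                   beta1 = cfg$beta1, beta2 = cfg$beta2, eps = cfg$epsilon)
  model$weights <- fit$weights
  structure(list(model = model, train_mse = fit$train_mse,
                 val_mse = fit$val_mse, best_epoch = fit$best_epoch,
                 best_val_mse = fit$best_val_mse, seed = as.integer(seed)),
            class = "rit_session")
}

#' Repeat training sessions and ensemble the session-best models
#'
#' Runs `cfg$n_repetitions` sessions seeded `base_seed, base_seed + 1, ...`
#' and collects each session's best-validation-epoch model into an ensemble.
#'
#' @inheritParams train_session
#' @param eccentricity_mm location annotation for the ensemble.
#' @return a [model_ensemble()] whose `sessions` field holds the
#'   `rit_session` results.
#' @export
run_repetitions <- function(train, val, cfg, eccentricity_mm = NA_real_) {
  sessions <- vector("list", cfg$n_repetitions)
  for (r in seq_len(cfg$n_repetitions)) {
    seed <- child_seed(cfg$base_seed, r - 1L)
    sessions[[r]] <- tryCatch(
      train_session(train, val, cfg, seed = seed),
      error = function(e) {
        rit_stop("ritmap_training_error", "repetition %d failed: %s",
                 r, conditionMessage(e))
      })
  }
  model_ensemble(lapply(sessions, `[[`, "model"),
                 eccentricity_mm = eccentricity_mm, sessions = sessions)
}

#' Write a per-epoch loss log
#' @param session a `rit_session`.
#' @param path CSV destination (columns epoch, train_mse, val_mse).
#' @export
write_loss_log <- function(session, path) {
  write.csv(data.frame(epoch = seq_along(session$train_mse),
                       train_mse = session$train_mse,
                       val_mse = session$val_mse),
            path, row.names = FALSE)
  invisible(path)
}
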