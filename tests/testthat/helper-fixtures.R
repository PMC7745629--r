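# Shared fixtures, built in code. Heavier objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# tiny architecture: fast to train/evaluate, same code paths
tiny_train_config <- function(...) {
  train_config("desk", conv_channels = c(2L, 4L), dense_width = 8L,
               n_repetitions = 2L, epochs = 5L, ...)
}

# deterministic noise-free phantom config for geometry tests
clean_phantom <- function(...) {
  phantom_config(speckle_shape = 0, rit_noise_sd_minutes = 0,
                 jitter_depth_sd_px = 0, ...)
}

# a small speckled cohort shared across tests
small_cohort <- function() {
  memo("small_cohort", {
    cfg <- phantom_config(seed = 77)
    list(cfg = cfg, cohort = sample_cohort(cfg, n_patients = 24),
         split = split_cohort(sprintf("P%04d", 1:24), seed = 77))
  })
}

# a synthetic image with hand-placed rows for placement tests
rowbar_image <- function(rows255, H = 300L, W = 100L) {
  px <- matrix(0L, H, W)
  px[rows255, ] <- 255L
  bscan_image(px, fovea_col = 50L, lateral_scale_mm_per_px = 0.01,
              axial_scale_mm_per_px = 0.004, volume_id = "rowbar")
}

# hand-crafted one-member "constant" model: all weights zero, output bias c
constant_model <- function(arch, value) {
  m <- build_model(arch, seed = 1L)
  m$weights <- lapply(m$weights, function(w) { w[] <- 0; w })
  m$weights[[length(m$weights)]][1, 1] <- value
  m
}
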