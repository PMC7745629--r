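tiny_ensemble <- function(seed = 1L) {
  memo("tiny_ensemble", {
    arch <- cnn_architecture(256L, 64L, c(2L, 4L), 8L)
    model_ensemble(list(build_model(arch, seed), build_model(arch, seed + 1L)),
                   eccentricity_mm = 0.3)
  })
}

test_that("occlude_patch implements the three fill rules exactly", {
  cfg <- occlusion_config(patch_w_px = 2L, patch_h_px = 2L)
  const <- matrix(42, 10, 10)
  expect_equal(occlude_patch(const, c(5L, 5L), cfg), const)
  px <- matrix(0, 10, 10)
  px[5:6, 5:6] <- c(0, 255, 0, 255)
  out <- occlude_patch(px, c(6L, 6L), cfg)  # patch rows 5:6, cols 5:6
  expect_equal(out[5:6, 5:6], matrix(127.5, 2, 2))
  expect_equal(out[-(5:6), ], px[-(5:6), ])
  zo <- occlude_patch(px, c(6L, 6L),
                      occlusion_config(2L, 2L, fill = "zero"))
  expect_equal(zo[5:6, 5:6], matrix(0, 2, 2))
  pe <- occlude_patch(px, c(6L, 6L),
                      occlusion_config(2L, 2L, fill = "permute",
                                       permute_seed = 4L))
  expect_equal(sort(pe[5:6, 5:6]), sort(px[5:6, 5:6]))
  expect_equal(pe[-(5:6), ], px[-(5:6), ])
  # border patches are cropped; the mean uses the cropped support
  big <- occlusion_config(patch_w_px = 6L, patch_h_px = 6L)
  m <- matrix(seq_len(16), 4, 4)
  out2 <- occlude_patch(m, c(1L, 1L), big)
  expect_equal(unique(as.numeric(out2[1:3, 1:3])), mean(m[1:3, 1:3]))
  expect_error(occlude_patch(m, c(0L, 1L), big), class = "ritmap_range_error")
})

test_that("fixed-window maps are zero off-support and match the oracle", {
  cfg <- clean_phantom(seed = 31)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0.7))
  ens <- tiny_ensemble()
  spec <- window_spec(0.3)
  oc <- occlusion_config(stride_px = 16L)
  prod <- occlusion_map(ens, im, spec, oc)
  naive <- occlusion_map_naive(ens, im, spec, oc)
  expect_identical(prod$evaluated, naive$evaluated)
  expect_lt(max(abs(prod$delta_rit_minutes - naive$delta_rit_minutes)), 1e-8)
  # unevaluated (patch disjoint from window) entries are exact zeros
  expect_true(all(prod$delta_rit_minutes[!prod$evaluated] == 0))
  expect_gt(sum(prod$evaluated), 0)
  # deltas are reported in minutes: 40x the normalized-output difference
  ctr <- which(prod$evaluated, arr.ind = TRUE)[1, ]
  pl <- ritmap:::frozen_placement(im, spec)
  pert <- occlude_patch(im$pixels, c(prod$row_centers[ctr[1]],
                                     prod$col_centers[ctr[2]]), oc)
  w <- pert[pl$rows, pl$cols] / 255
  d_norm <- mean(vapply(ens$models, function(m)
    predict_model(m, w), numeric(1))) -
    mean(vapply(ens$models, function(m)
      predict_model(m, pl$window$patch), numeric(1)))
  expect_equal(prod$delta_rit_minutes[ctr[1], ctr[2]], 40 * d_norm)
})

test_that("mean occlusion of a constant image is a no-op everywhere", {
  cfg <- clean_phantom(seed = 1)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0))
  im$pixels[] <- 99L
  m <- occlusion_map(tiny_ensemble(), im, window_spec(0),
                     occlusion_config(stride_px = 8L))
  expect_true(all(m$delta_rit_minutes == 0))
})

test_that("sliding-window maps cover the full lateral extent", {
  cfg <- clean_phantom(seed = 5)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0.5))
  oc <- occlusion_config(stride_px = 32L, inference_mode = "sliding_window")
  m <- occlusion_map(tiny_ensemble(), im, window_spec(0.3), oc)
  fits <- m$col_centers - 32L >= 1L &
    m$col_centers + 31L <= ncol(im$pixels)
  expect_true(all(m$evaluated[, fits]))
  expect_true(all(!m$evaluated[, !fits]))
})

test_that("permute fill is reproducible from its seed", {
  cfg <- clean_phantom(seed = 2)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0.9))
  oc <- occlusion_config(fill = "permute", stride_px = 32L, permute_seed = 7L)
  m1 <- occlusion_map(tiny_ensemble(), im, window_spec(0.3), oc)
  m2 <- occlusion_map(tiny_ensemble(), im, window_spec(0.3), oc)
  expect_identical(m1$delta_rit_minutes, m2$delta_rit_minutes)
})

test_that("overlay rendering follows the sign convention", {
  cfg <- clean_phantom(seed = 3)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0))
  H <- nrow(im$pixels); W <- ncol(im$pixels)
  zero_map <- structure(list(delta_rit_minutes = matrix(0, H, W),
                             row_centers = 1:H, col_centers = 1:W,
                             evaluated = matrix(TRUE, H, W),
                             image_dims = c(H, W)),
                        class = "occlusion_map")
  ov <- render_overlay(zero_map, im)
  expect_equal(ov[, , 1], im$pixels / 255)
  expect_equal(ov[, , 1], ov[, , 2])
  expect_equal(ov[, , 2], ov[, , 3])
  pos_map <- zero_map
  pos_map$delta_rit_minutes[100, 50] <- 2
  pos_map$delta_rit_minutes[200, 60] <- -2
  ov2 <- render_overlay(pos_map, im)
  expect_gt(ov2[100, 50, 1], ov2[100, 50, 3])  # lengthening -> red
  expect_gt(ov2[200, 60, 3], ov2[200, 60, 1])  # shortening -> blue
  # sign flip swaps the channels
  neg_map <- pos_map
  neg_map$delta_rit_minutes <- -pos_map$delta_rit_minutes
  ov3 <- render_overlay(neg_map, im)
  expect_equal(ov3[100, 50, 3], ov2[100, 50, 1])
  expect_equal(ov3[200, 60, 1], ov2[200, 60, 3])
})

test_that("band swapping replaces exactly the masked pixels", {
  cfg <- clean_phantom(seed = 4)
  hi <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 1))
  lo <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0))
  msk <- biomarker_mask(cfg, eye_params("P1", "P1_OD", b = 1))
  sw <- swap_band_pixels(hi, lo, msk)
  expect_identical(sw$pixels[msk], lo$pixels[msk])
  expect_identical(sw$pixels[!msk], hi$pixels[!msk])
  expect_error(swap_band_pixels(hi, lo, msk[1:10, ]),
               class = "ritmap_shape_error")
})

test_that("sensitivity suite compares fills and sizes over aligned grids", {
  cfg <- clean_phantom(seed = 8)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0.8))
  out <- sensitivity_suite(tiny_ensemble(), list(im), window_spec(0.3),
                           occlusion_config(stride_px = 24L))
  expect_setequal(names(out$variants),
                  c("fill_mean", "fill_zero", "fill_permute",
                    "size_8x3", "size_32x12"))
  co <- out$correlations
  expect_equal(nrow(co), choose(5, 2))
  expect_true(all(co$spearman >= -1 & co$spearman <= 1, na.rm = TRUE))
  expect_false(any(co$degenerate))
  # identical configurations correlate perfectly with themselves
  mm <- occlusion_map(tiny_ensemble(), im, window_spec(0.3),
                      occlusion_config(stride_px = 24L))
  v <- abs(mm$delta_rit_minutes[mm$evaluated])
  expect_equal(cor(v, v, method = "spearman"), 1)
  # all-constant images give all-zero maps, reported as degenerate
  imc <- im; imc$pixels[] <- 50L
  outc <- sensitivity_suite(tiny_ensemble(), list(imc), window_spec(0.3),
                            occlusion_config(stride_px = 48L))
  expect_true(all(outc$correlations$degenerate))
  expect_true(all(is.na(outc$correlations$spearman)))
})

test_that("map CSV lists evaluated positions with their deltas", {
  cfg <- clean_phantom(seed = 6)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 0.5))
  m <- occlusion_map(tiny_ensemble(), im, window_spec(0.3),
                     occlusion_config(stride_px = 32L))
  path <- tempfile(fileext = ".csv")
  write_map_csv(m, path)
  df <- read.csv(path)
  expect_equal(nrow(df), sum(m$evaluated))
  i <- which(m$row_centers == df$row[1])
  j <- which(m$col_centers == df$col[1])
  expect_equal(df$delta_rit_minutes[1], m$delta_rit_minutes[i, j])
})
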