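test_that("eccentricity <-> column conversion is exact and symmetric", {
  im <- rowbar_image(150L, H = 300L, W = 400L)
  im$fovea_col <- 192L
  expect_equal(eccentricity_to_col(0, im), 192L)
  expect_equal(eccentricity_to_col(0.34, im), 192L + 34L)
  expect_equal(eccentricity_to_col(-0.34, im), 192L - 34L)
  expect_equal(col_to_eccentricity(226L, im), 0.34)
  # half-away-from-zero rounding, symmetric about the fovea
  expect_equal(eccentricity_to_col(0.005, im) - 192L, 1L)
  expect_equal(eccentricity_to_col(-0.005, im) - 192L, -1L)
  err <- expect_error(eccentricity_to_col(5, im, half_width_px = 32L),
                      class = "ritmap_range_error")
  expect_match(conditionMessage(err), "allowed span")
})

test_that("vertical center is the MIP argmax with first-row tie-break", {
  expect_equal(compute_vertical_center(rowbar_image(100L), 1:100), 100L)
  expect_equal(compute_vertical_center(rowbar_image(c(80L, 120L)), 1:100), 80L)
  flat <- rowbar_image(integer(0))
  expect_equal(compute_vertical_center(flat, 10:20), 1L)
  expect_error(compute_vertical_center(flat, integer(0)),
               class = "ritmap_domain_error")
  expect_error(compute_vertical_center(flat, 90:110),
               class = "ritmap_domain_error")
})

test_that("extract_window obeys shape, normalization and placement", {
  # bright row at 180 in a 496-row image: window rows 52..307, center local 128
  im <- rowbar_image(180L, H = 496L, W = 200L)
  im$fovea_col <- 100L
  w <- extract_window(im, window_spec(0), rit_minutes = 20)
  expect_equal(dim(w$patch), c(256L, 64L))
  expect_equal(w$rows, c(52L, 307L))
  expect_equal(which(w$patch[, 1] == 1), 180L - 52L + 1L)  # local row 129
  expect_equal(w$label, 0.5)
  expect_true(all(w$patch >= 0 & w$patch <= 1))
  # all-255 image gives an all-1 patch
  allb <- rowbar_image(1:496, H = 496L, W = 200L)
  expect_true(all(extract_window(allb, window_spec(0))$patch == 1))
  # vertical overhang is shifted minimally to fit
  top <- rowbar_image(10L, H = 496L, W = 200L)
  expect_equal(extract_window(top, window_spec(0))$rows, c(1L, 256L))
  bot <- rowbar_image(490L, H = 496L, W = 200L)
  expect_equal(extract_window(bot, window_spec(0))$rows, c(241L, 496L))
  # lateral overhang errors (no padding)
  expect_error(extract_window(im, window_spec(0.95)),
               class = "ritmap_extraction_error")
})

test_that("window placement is mirror-symmetric about the fovea", {
  # flat bands so the MIP row is column-independent; the biomarker at
  # +0.3 mm gives the image lateral structure
  cfg <- clean_phantom(pit_depth_px = 0, seed = 2)
  im <- generate_bscan(cfg, eye_params("P1", "P1_OD", b = 1))
  W <- ncol(im$pixels)
  mirrored <- im
  mirrored$pixels <- im$pixels[, W:1]
  mirrored$fovea_col <- W - im$fovea_col + 1L
  for (e in c(0.3, 0.75)) {
    a <- extract_window(im, window_spec(e))
    b <- extract_window(mirrored, window_spec(-e))
    # window centers are mirror columns; rows agree
    expect_equal(b$cols[1] + 32L, W + 1L - (a$cols[1] + 32L))
    expect_equal(b$rows, a$rows)
    # contents mirror up to the one-column asymmetry of an even window
    expect_equal(b$patch[, 2:64], a$patch[, 64:2])
  }
})

test_that("patient-level split has exact counts and full inheritance", {
  sp <- split_cohort(sprintf("P%03d", 1:100), seed = 4)
  expect_equal(unname(table(sp)[c("train", "val", "test")]),
               c(60L, 20L, 20L), ignore_attr = TRUE)
  sp715 <- split_cohort(sprintf("P%03d", 1:715), seed = 4)
  expect_equal(unname(table(sp715)[c("train", "val", "test")]),
               c(429L, 143L, 143L), ignore_attr = TRUE)
  # volumes inherit the patient split
  rec <- data.frame(patient_id = rep(c("A", "B", "C", "D"), each = 4))
  spv <- split_cohort(rec, seed = 1)
  by_pat <- unname(spv[rec$patient_id])
  expect_equal(length(unique(by_pat[rec$patient_id == "A"])), 1L)
  # mutual exclusivity: one assignment per patient
  expect_equal(sort(names(spv)), sort(c("A", "B", "C", "D")))
  expect_false(any(duplicated(names(spv))))
  expect_error(split_cohort(sprintf("P%d", 1:10), fractions = c(0.5, 0.2, 0.2)),
               class = "ritmap_config_error")
  expect_error(split_cohort(c("A", "B"), seed = 1),
               class = "ritmap_data_error")
})

test_that("window datasets stack patches deterministically", {
  fx <- small_cohort()
  ds1 <- build_window_dataset(fx$cohort, 0.3, split = fx$split)
  ds2 <- build_window_dataset(fx$cohort, 0.3, split = fx$split)
  expect_identical(ds1$x, ds2$x)
  expect_equal(dim(ds1$x), c(256L * 64L, 24L))
  expect_equal(ds1$y, fx$cohort$records$rit_minutes / 40)
  expect_true(all(ds1$manifest$split %in% c("train", "val", "test")))
})
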