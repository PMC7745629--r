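#' B-scan image container
#'
#' One registered foveal B-scan: an 8-bit intensity matrix (rows = axial
#' depth, top = vitreous; columns = lateral position) with its pixel pitch,
#' the 1-based column of the foveal center, and source identifiers. Signed
#' eccentricity is measured laterally from `fovea_col` in mm, nasal positive
#' and temporal negative.
#'
#' @param pixels integer matrix of intensities in \[0, 255\].
#' @param fovea_col 1-based foveal column index.
#' @param lateral_scale_mm_per_px,axial_scale_mm_per_px pixel pitch, mm/px.
#' @param patient_id,eye_id,volume_id source identifiers.
#' @param ... extra metadata fields (e.g. ground-truth `b` for phantoms).
#' @return object of class `bscan_image`.
#' @export
bscan_image <- function(pixels, fovea_col, lateral_scale_mm_per_px,
                        axial_scale_mm_per_px, patient_id = NA_character_,
                        eye_id = NA_character_, volume_id = NA_character_,
                        ...) {
  if (!is.matrix(pixels)) rit_stop("ritmap_data_error", "pixels must be a matrix")
  if (min(pixels) < 0 || max(pixels) > 255) {
    rit_stop("ritmap_data_error", "pixel intensities must lie in [0, 255]")
  }
  fovea_col <- as.integer(fovea_col)
  if (fovea_col < 1L || fovea_col > ncol(pixels)) {
    rit_stop("ritmap_data_error", "fovea_col %d outside 1..%d",
             fovea_col, ncol(pixels))
  }
  stopifnot_scalar_num(lateral_scale_mm_per_px, "lateral_scale_mm_per_px", 1e-9)
  stopifnot_scalar_num(axial_scale_mm_per_px, "axial_scale_mm_per_px", 1e-9)
  structure(list(pixels = pixels, fovea_col = fovea_col,
                 lateral_scale_mm_per_px = lateral_scale_mm_per_px,
                 axial_scale_mm_per_px = axial_scale_mm_per_px,
                 patient_id = as.character(patient_id),
                 eye_id = as.character(eye_id),
                 volume_id = as.character(volume_id), ...),
            class = "bscan_image")
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("<bscan_image %s: %d x %d px, fovea col %d, %.4f x %.4f mm/px>\n",
              x$volume_id, nrow(x$pixels), ncol(x$pixels), x$fovea_col,
              x$axial_scale_mm_per_px, x$lateral_scale_mm_per_px))
  invisible(x)
}

#' Training-window specification
#'
#' A narrow anatomically restricted window: `width_px` lateral columns
#' centered on a signed eccentricity, `height_px` axial rows centered on the
#' horizontal maximum-intensity-projection row of those columns.
#'
#' @param center_eccentricity_mm signed eccentricity of the window center.
#' @param width_px lateral width (even), default 64.
#' @param height_px axial height (even), default 256.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(center_eccentricity_mm, width_px = 64L,
                        height_px = 256L) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 2L || height_px < 2L ||
      width_px %% 2L != 0L || height_px %% 2L != 0L) {
    rit_stop("ritmap_config_error", "window dims must be positive and even")
  }
  structure(list(center_eccentricity_mm = center_eccentricity_mm,
                 width_px = width_px, height_px = height_px,
                 placement = "mip_argmax"),
            class = "window_spec")
}

#' Convert signed eccentricity to a column index
#'
#' `col = fovea_col + round_half_away(ecc / lateral_scale)`. Errors when the
#' column (with `half_width_px` margin on both sides) leaves the image,
#' naming the admissible eccentricity span.
#'
#' @param ecc_mm signed eccentricity, mm (nasal positive).
#' @param image a [bscan_image()].
#' @param half_width_px lateral margin that must remain in-field.
#' @return 1-based column index.
#' @export
eccentricity_to_col <- function(ecc_mm, image, half_width_px = 0L) {
  col <- image$fovea_col + round_half_away(ecc_mm / image$lateral_scale_mm_per_px)
  W <- ncol(image$pixels)
  lo <- 1L + half_width_px; hi <- W - half_width_px
  if (col < lo || col > hi) {
    sc <- image$lateral_scale_mm_per_px
    rit_stop("ritmap_range_error",
             "eccentricity %.3f mm outside allowed span [%.3f, %.3f] mm",
             ecc_mm, (lo - image$fovea_col) * sc, (hi - image$fovea_col) * sc)
  }
  col
}

#' Inverse of [eccentricity_to_col()]
#' @param col 1-based column index.
#' @param image a [bscan_image()].
#' @return signed eccentricity, mm.
#' @export
col_to_eccentricity <- function(col, image) {
  (col - image$fovea_col) * image$lateral_scale_mm_per_px
}

#' Axial center via horizontal maximum intensity projection
#'
#' Pools the columns `cols` into one axial profile (across-column mean) and
#' returns the row of its maximum; ties break to the smallest row index, so
#' a constant image yields row 1.
#'
#' @param image a [bscan_image()].
#' @param cols integer vector of column indices (non-empty, in-bounds).
#' @return 1-based row index.
#' @export
compute_vertical_center <- function(image, cols) {
  if (length(cols) == 0L) {
    rit_stop("ritmap_domain_error", "empty column range")
  }
  if (min(cols) < 1L || max(cols) > ncol(image$pixels)) {
    rit_stop("ritmap_domain_error", "column range outside image")
  }
  profile <- rowMeans(image$pixels[, cols, drop = FALSE])
  which.max(profile)  # which.max returns the first (smallest) maximizer
}

#' Extract one anatomically restricted training window
#'
#' Lateral extent: `width_px` columns centered on the spec eccentricity
#' (strict — lateral overhang is an error, never padded). Axial extent:
#' `height_px` rows centered on the MIP row of those columns, shifted
#' minimally to fit the image when it would overhang. Pixel intensities are
#' divided by 255; the RIT label, when given, is divided by 40 minutes.
#'
#' @param image a [bscan_image()].
#' @param spec a [window_spec()].
#' @param rit_minutes optional RIT label for this volume, minutes.
#' @return object of class `training_window`: `patch` (height x width in
#'   \[0, 1\]), `label` (RIT/40 or NA), placement bookkeeping and source ids.
#' @export
extract_window <- function(image, spec, rit_minutes = NA_real_) {
  half_w <- spec$width_px %/% 2L
  center_col <- image$fovea_col +
    round_half_away(spec$center_eccentricity_mm / image$lateral_scale_mm_per_px)
  c0 <- center_col - half_w
  c1 <- c0 + spec$width_px - 1L
  if (c0 < 1L || c1 > ncol(image$pixels)) {
    rit_stop("ritmap_extraction_error",
             "window at %.3f mm overhangs laterally (cols %d..%d of %d)",
             spec$center_eccentricity_mm, c0, c1, ncol(image$pixels))
  }
  H <- nrow(image$pixels)
  if (spec$height_px > H) {
    rit_stop("ritmap_extraction_error",
             "window height %d exceeds image height %d", spec$height_px, H)
  }
  mip_row <- compute_vertical_center(image, c0:c1)
  r0 <- mip_row - spec$height_px %/% 2L
  r0 <- min(max(r0, 1L), H - spec$height_px + 1L)  # minimal shift to fit
  r1 <- r0 + spec$height_px - 1L
  structure(list(
    patch = image$pixels[r0:r1, c0:c1, drop = FALSE] / 255,
    label = if (is.na(rit_minutes)) NA_real_ else rit_minutes / 40,
    rit_minutes = rit_minutes,
    rows = c(r0, r1), cols = c(c0, c1), mip_row = mip_row,
    center_eccentricity_mm = spec$center_eccentricity_mm,
    patient_id = image$patient_id, eye_id = image$eye_id,
    volume_id = image$volume_id
  ), class = "training_window")
}

#' Patient-level train/validation/test split
#'
#' Randomly assigns whole patients to splits with counts
#' `(round(f1 * n), round(f2 * n), remainder)`; every eye and volume of a
#' patient inherits that patient's split, so the three sets are mutually
#' exclusive at the patient level.
#'
#' @param records data.frame with a `patient_id` column (one row per
#'   volume), or a character vector of patient ids.
#' @param fractions length-3 numeric summing to 1 (default 0.6/0.2/0.2).
#' @param seed RNG seed for the assignment.
#' @return named character vector `patient_id -> "train"|"val"|"test"`.
#' @export
split_cohort <- function(records, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    rit_stop("ritmap_config_error", "fractions must be length 3 and sum to 1")
  }
  patients <- if (is.data.frame(records)) unique(records$patient_id)
              else unique(as.character(records))
  n <- length(patients)
  if (n < 3L) rit_stop("ritmap_data_error", "need at least 3 patients to split")
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    rit_stop("ritmap_data_error", "split would leave an empty set (n = %d)", n)
  }
  set.seed(seed)
  shuffled <- sample(patients)
  assignment <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  stats::setNames(assignment, shuffled)[patients]
}

#' Build the window dataset for one eccentricity
#'
#' Extracts the window at `ecc_mm` from every cohort image and stacks the
#' patches into the flat matrix layout the trainer consumes (one column per
#' window, pixels in column-major order, values in \[0, 1\]).
#'
#' @param cohort list with `images` and `records` as from [sample_cohort()].
#' @param ecc_mm signed window-center eccentricity, mm.
#' @param split optional named split vector from [split_cohort()]; when
#'   given, a `split` column is attached to the manifest.
#' @param width_px,height_px window dimensions.
#' @return list: `x` (pixels x n matrix), `y` (normalized labels, RIT/40),
#'   `manifest` (data.frame of ids, labels and placements), `height_px`,
#'   `width_px`.
#' @export
build_window_dataset <- function(cohort, ecc_mm, split = NULL,
                                 width_px = 64L, height_px = 256L) {
  spec <- window_spec(ecc_mm, width_px, height_px)
  n <- length(cohort$images)
  stopifnot(n == nrow(cohort$records))
  x <- matrix(0, nrow = height_px * width_px, ncol = n)
  rows <- integer(n)
  for (i in seq_len(n)) {
    w <- extract_window(cohort$images[[i]], spec,
                        rit_minutes = cohort$records$rit_minutes[i])
    x[, i] <- as.numeric(w$patch)
    rows[i] <- w$rows[1]
  }
  manifest <- cohort$records
  manifest$window_row0 <- rows
  manifest$ecc_mm <- ecc_mm
  if (!is.null(split)) manifest$split <- unname(split[manifest$patient_id])
  list(x = x, y = cohort$records$rit_minutes / 40, manifest = manifest,
       height_px = as.integer(height_px), width_px = as.integer(width_px))
}

# Subset a window dataset by manifest predicate (internal).
subset_windows <- function(ds, keep) {
  list(x = ds$x[, keep, drop = FALSE], y = ds$y[keep],
       manifest = ds$manifest[keep, , drop = FALSE],
       height_px = ds$height_px, width_px = ds$width_px)
}
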