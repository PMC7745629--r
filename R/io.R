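#' Write a phantom cohort to disk
#'
#' Images as 8-bit grayscale PGM files plus a `labels.csv` sidecar with one
#' row per volume: patient_id, eye_id, volume_id, path, fovea_col,
#' lateral_scale_mm_per_px, axial_scale_mm_per_px, rit_minutes and, when a
#' split is supplied, the split label.
#'
#' @param cohort list from [sample_cohort()].
#' @param dir destination directory (created if missing).
#' @param split optional named split vector from [split_cohort()].
#' @return path of the written CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$images)
  paths <- character(n)
  for (i in seq_len(n)) {
    im <- cohort$images[[i]]
    paths[i] <- file.path("images", paste0(im$volume_id, ".pgm"))
    write_pgm(im$pixels, file.path(dir, paths[i]))
  }
  df <- data.frame(
    patient_id = cohort$records$patient_id,
    eye_id = cohort$records$eye_id,
    volume_id = cohort$records$volume_id,
    path = paths,
    fovea_col = vapply(cohort$images, `[[`, integer(1), "fovea_col"),
    lateral_scale_mm_per_px = vapply(cohort$images, `[[`, numeric(1),
                                     "lateral_scale_mm_per_px"),
    axial_scale_mm_per_px = vapply(cohort$images, `[[`, numeric(1),
                                   "axial_scale_mm_per_px"),
    rit_minutes = cohort$records$rit_minutes,
    stringsAsFactors = FALSE)
  if (!is.null(split)) df$split <- unname(split[df$patient_id])
  csv <- file.path(dir, "labels.csv")
  write.csv(df, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort written by [write_cohort()]
#'
#' Any directory with the same layout (PGM images + `labels.csv`) is
#' accepted, so externally exported B-scans can be ingested the same way.
#'
#' @param dir cohort directory.
#' @return list with `images` and `records`, as [sample_cohort()].
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "labels.csv")
  if (!file.exists(csv)) {
    rit_stop("ritmap_data_error", "no labels.csv under %s", dir)
  }
  df <- read.csv(csv, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(df)), function(i) {
    bscan_image(pixels = read_pgm(file.path(dir, df$path[i])),
                fovea_col = df$fovea_col[i],
                lateral_scale_mm_per_px = df$lateral_scale_mm_per_px[i],
                axial_scale_mm_per_px = df$axial_scale_mm_per_px[i],
                patient_id = df$patient_id[i], eye_id = df$eye_id[i],
                volume_id = df$volume_id[i])
  })
  records <- df[, c("patient_id", "eye_id", "volume_id", "rit_minutes")]
  list(images = images, records = records,
       split = if ("split" %in% names(df))
         stats::setNames(df$split, df$patient_id)[!duplicated(df$patient_id)]
       else NULL)
}

#' Serialize an ensemble to JSON
#'
#' Stores the architecture, per-member weights, session seeds, the fixed
#' normalization constants (255 for inputs, 40 minutes for the label) and
#' the training eccentricity, so a saved ensemble is self-describing.
#'
#' @param ensemble a [model_ensemble()].
#' @param path JSON destination.
#' @export
write_ensemble_json <- function(ensemble, path) {
  obj <- list(
    format = "ritmap_ensemble_v1",
    eccentricity_mm = ensemble$eccentricity_mm,
    input_scale = 255, label_scale_minutes = 40,
    arch = unclass(ensemble$models[[1]]$arch),
    members = lapply(ensemble$models, function(m) {
      list(seed = m$seed, weights = lapply(m$weights, identity))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @return a [model_ensemble()].
#' @export
read_ensemble_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ritmap_ensemble_v1")) {
    rit_stop("ritmap_data_error", "%s is not a ritmap ensemble file", path)
  }
  arch <- cnn_architecture(obj$arch$height_px, obj$arch$width_px,
                           obj$arch$conv_channels, obj$arch$dense_width,
                           pooling = obj$arch$pooling)
  # jsonlite simplifies the member list to a data.frame-like list; handle both
  raw_members <- if (is.data.frame(obj$members)) {
    lapply(seq_len(nrow(obj$members)), function(i)
      list(seed = obj$members$seed[i], weights = obj$members$weights[[i]]))
  } else {
    obj$members
  }
  models <- lapply(raw_members, function(m) {
    w <- lapply(m$weights, function(x) {
      x <- as.matrix(x)
      storage.mode(x) <- "double"
      x
    })
    structure(list(arch = arch, weights = w, seed = as.integer(m$seed)),
              class = "rit_cnn")
  })
  model_ensemble(models, eccentricity_mm = obj$eccentricity_mm)
}
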