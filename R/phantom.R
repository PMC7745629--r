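#' Default outer-retinal layer geometry
#'
#' Stacked horizontal reflectivity bands of a foveal B-scan phantom, ordered
#' from the vitreous downward. `offset_px` is the band's top row (1-based) at
#' zero pit displacement, `thickness_px` its axial extent, `intensity` its
#' mean reflectivity on the 8-bit scale. The outer-retinal hyperreflective
#' bands (ELM, EZ, IZ, RPE-BrM) are separated by the two hyporeflective bands
#' that carry the injected biomarker: the inner-segment myoid zone above the
#' EZ and the unnamed gap between the EZ and the IZ below it.
#'
#' @return data.frame with columns `band`, `offset_px`, `thickness_px`,
#'   `intensity`.
#' @export
default_layer_geometry <- function() {
  data.frame(
    band = c("inner_retina", "onl", "elm", "myoid", "ez",
             "subez_gap", "iz", "rpe_brm", "choroid"),
    offset_px = c(60L, 220L, 280L, 284L, 292L, 300L, 306L, 312L, 324L),
    thickness_px = c(160L, 60L, 4L, 8L, 8L, 6L, 6L, 12L, 80L),
    intensity = c(110, 30, 150, 40, 200, 40, 130, 210, 60),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Describes the simulated B-scan geometry, reflectivity, speckle, the
#' injected biomarker, and the link from latent biomarker strength to the
#' rod intercept time (RIT) label.
#'
#' The biomarker raises the mean intensity of the two hyporeflective bands
#' flanking the ellipsoid zone (`myoid` and `subez_gap`) by
#' `b * biomarker_contrast` inside a lateral footprint
#' `|eccentricity - biomarker_center_mm| <= biomarker_width_mm / 2`,
#' emulating the blunting of the EZ/RPE distinction seen in eyes with slow
#' rod-mediated dark adaptation. RIT labels are affine in strength `b`
#' between `rit_min_minutes` and `rit_max_minutes` (the 40-minute
#' normalization ceiling) plus Gaussian noise.
#'
#' @param image_width_px,image_height_px image dimensions in pixels.
#' @param lateral_scale_mm_per_px,axial_scale_mm_per_px pixel pitch, mm/px.
#' @param fovea_col 1-based column of the foveal center.
#' @param layer_geometry data.frame as [default_layer_geometry()].
#' @param vitreous_intensity,sub_rpe_intensity background reflectivity above
#'   the inner retinal surface and below the deepest band.
#' @param pit_depth_px peak downward displacement of all bands at the fovea.
#' @param pit_sigma_mm lateral Gaussian width of the foveal pit, mm.
#' @param biomarker_center_mm signed eccentricity of the biomarker center
#'   (nasal positive, temporal negative), mm.
#' @param biomarker_width_mm lateral footprint width, mm.
#' @param biomarker_contrast intensity shift of the two hyporeflective bands
#'   per unit strength, 8-bit units.
#' @param speckle_shape gamma shape of the multiplicative speckle
#'   (mean 1, variance 1/shape); `0` disables speckle. For frame-averaged
#'   OCT the shape is approximately the number of averaged frames (sums of
#'   unit-mean exponential speckle are gamma), so the default 12 emulates a
#'   mid-range automatic real-time averaging setting.
#' @param rit_min_minutes,rit_max_minutes RIT label range (affine in `b`).
#' @param rit_noise_sd_minutes additive label noise SD, minutes.
#' @param jitter_depth_sd_px per-eye axial jitter SD applied to all bands.
#' @param seed integer seed anchoring all cohort randomness.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_width_px = 384L,
                           image_height_px = 496L,
                           lateral_scale_mm_per_px = 0.015,
                           axial_scale_mm_per_px = 0.0039,
                           fovea_col = NULL,
                           layer_geometry = default_layer_geometry(),
                           vitreous_intensity = 8,
                           sub_rpe_intensity = 25,
                           pit_depth_px = 30,
                           pit_sigma_mm = 0.35,
                           biomarker_center_mm = 0.3,
                           biomarker_width_mm = 0.5,
                           biomarker_contrast = 80,
                           speckle_shape = 12,
                           rit_min_minutes = 5,
                           rit_max_minutes = 40,
                           rit_noise_sd_minutes = 1,
                           jitter_depth_sd_px = 2,
                           seed = 1L) {
  if (is.null(fovea_col)) fovea_col <- as.integer(image_width_px / 2)
  cfg <- list(
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    lateral_scale_mm_per_px = lateral_scale_mm_per_px,
    axial_scale_mm_per_px = axial_scale_mm_per_px,
    fovea_col = as.integer(fovea_col),
    layer_geometry = layer_geometry,
    vitreous_intensity = vitreous_intensity,
    sub_rpe_intensity = sub_rpe_intensity,
    pit_depth_px = pit_depth_px,
    pit_sigma_mm = pit_sigma_mm,
    biomarker_center_mm = biomarker_center_mm,
    biomarker_width_mm = biomarker_width_mm,
    biomarker_contrast = biomarker_contrast,
    speckle_shape = speckle_shape,
    rit_min_minutes = rit_min_minutes,
    rit_max_minutes = rit_max_minutes,
    rit_noise_sd_minutes = rit_noise_sd_minutes,
    jitter_depth_sd_px = jitter_depth_sd_px,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot_scalar_num(cfg$image_width_px, "image_width_px", lo = 1)
  stopifnot_scalar_num(cfg$image_height_px, "image_height_px", lo = 1)
  stopifnot_scalar_num(cfg$lateral_scale_mm_per_px, "lateral_scale_mm_per_px",
                       lo = 1e-6)
  stopifnot_scalar_num(cfg$axial_scale_mm_per_px, "axial_scale_mm_per_px",
                       lo = 1e-6)
  if (cfg$fovea_col < 1L || cfg$fovea_col > cfg$image_width_px) {
    rit_stop("ritmap_config_error", "fovea_col %d outside image width %d",
             cfg$fovea_col, cfg$image_width_px)
  }
  lg <- cfg$layer_geometry
  need <- c("band", "offset_px", "thickness_px", "intensity")
  if (!is.data.frame(lg) || !all(need %in% names(lg))) {
    rit_stop("ritmap_config_error",
             "layer_geometry must have columns band/offset_px/thickness_px/intensity")
  }
  if (any(lg$intensity < 0 | lg$intensity > 255)) {
    rit_stop("ritmap_config_error", "band intensities must lie in [0, 255]")
  }
  if (!all(c("myoid", "subez_gap") %in% lg$band)) {
    rit_stop("ritmap_config_error",
             "layer_geometry must contain the 'myoid' and 'subez_gap' bands")
  }
  if (!(cfg$rit_min_minutes < cfg$rit_max_minutes &&
        cfg$rit_max_minutes <= 40)) {
    rit_stop("ritmap_config_error",
             "need rit_min_minutes < rit_max_minutes <= 40")
  }
  stopifnot_scalar_num(cfg$rit_noise_sd_minutes, "rit_noise_sd_minutes", lo = 0)
  stopifnot_scalar_num(cfg$speckle_shape, "speckle_shape", lo = 0)
  # biomarker footprint must fit inside the lateral field of view
  half_w <- cfg$biomarker_width_mm / 2
  span <- fov_span_mm(cfg)
  if (cfg$biomarker_center_mm - half_w < span[1] ||
      cfg$biomarker_center_mm + half_w > span[2]) {
    rit_stop("ritmap_config_error",
             "biomarker footprint [%.2f, %.2f] mm outside lateral field [%.2f, %.2f] mm",
             cfg$biomarker_center_mm - half_w, cfg$biomarker_center_mm + half_w,
             span[1], span[2])
  }
  invisible(cfg)
}

# Signed eccentricity range covered by the image columns, mm.
fov_span_mm <- function(cfg) {
  c(1L - cfg$fovea_col, cfg$image_width_px - cfg$fovea_col) *
    cfg$lateral_scale_mm_per_px
}

#' Per-eye phantom parameters
#'
#' Latent per-eye state: a biomarker strength `b` in \[0, 1\] standing in for
#' the disease-severity spectrum, plus a small axial geometry jitter so that
#' eyes are not pixel-identical.
#'
#' @param patient_id,eye_id identifiers; both eyes of a patient share
#'   `patient_id`.
#' @param b biomarker strength in \[0, 1\].
#' @param depth_jitter_px axial band displacement for this eye, px.
#' @return object of class `eye_params`.
#' @export
eye_params <- function(patient_id, eye_id, b, depth_jitter_px = 0) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0 || b > 1) {
    rit_stop("ritmap_domain_error", "biomarker strength b must lie in [0, 1]")
  }
  structure(list(patient_id = as.character(patient_id),
                 eye_id = as.character(eye_id),
                 b = b, depth_jitter_px = depth_jitter_px),
            class = "eye_params")
}

#' Link biomarker strength to a rod intercept time label
#'
#' Affine link with additive Gaussian noise:
#' `RIT = rit_min + b * (rit_max - rit_min) + N(0, sd)`, truncated below at
#' 0.1 minutes. With `sd = 0` the label is an exact affine function of `b`.
#' Draws from the current R RNG stream.
#'
#' @param b biomarker strength in \[0, 1\].
#' @param cfg a [phantom_config()].
#' @return RIT in minutes.
#' @export
rit_link <- function(b, cfg) {
  if (!is.numeric(b) || any(is.na(b)) || any(b < 0 | b > 1)) {
    rit_stop("ritmap_domain_error", "biomarker strength b must lie in [0, 1]")
  }
  rit <- cfg$rit_min_minutes +
    b * (cfg$rit_max_minutes - cfg$rit_min_minutes)
  if (cfg$rit_noise_sd_minutes > 0) {
    rit <- rit + rnorm(length(b), 0, cfg$rit_noise_sd_minutes)
  }
  pmax(rit, 0.1)
}

# Axial displacement of all bands at each column: Gaussian foveal pit plus
# the eye's jitter. Returns a numeric vector over columns.
band_shift_px <- function(cfg, eye) {
  ecc <- (seq_len(cfg$image_width_px) - cfg$fovea_col) *
    cfg$lateral_scale_mm_per_px
  cfg$pit_depth_px * exp(-ecc^2 / (2 * cfg$pit_sigma_mm^2)) +
    eye$depth_jitter_px
}

# Columns inside the biomarker's lateral footprint.
footprint_cols <- function(cfg) {
  ecc <- (seq_len(cfg$image_width_px) - cfg$fovea_col) *
    cfg$lateral_scale_mm_per_px
  which(abs(ecc - cfg$biomarker_center_mm) <= cfg$biomarker_width_mm / 2)
}

#' Render one phantom B-scan
#'
#' Draws the layered reflectivity bands with a Gaussian foveal pit, raises
#' the two hyporeflective bands flanking the EZ by `b * biomarker_contrast`
#' inside the biomarker footprint, applies multiplicative gamma speckle
#' (current R RNG stream), clips to \[0, 255\] and rounds to 8 bits.
#'
#' @param cfg a [phantom_config()].
#' @param eye an [eye_params()].
#' @param volume_id volume identifier recorded in the image metadata.
#' @return a [bscan_image()].
#' @export
generate_bscan <- function(cfg, eye, volume_id = paste0(eye$eye_id, "_V1")) {
  validate_phantom_config(cfg)
  H <- cfg$image_height_px; W <- cfg$image_width_px
  lg <- cfg$layer_geometry
  shift <- band_shift_px(cfg, eye)
  fp <- footprint_cols(cfg)

  img <- matrix(cfg$vitreous_intensity, nrow = H, ncol = W)
  rowm <- matrix(seq_len(H), H, W)
  in_fp <- matrix(seq_len(W) %in% fp, H, W, byrow = TRUE)
  nb <- nrow(lg)
  for (bi in seq_len(nb)) {
    top <- matrix(lg$offset_px[bi] + shift, H, W, byrow = TRUE)
    sel <- rowm >= top & rowm < top + lg$thickness_px[bi]
    img[sel] <- lg$intensity[bi]
    if (lg$band[bi] %in% c("myoid", "subez_gap")) {
      img[sel & in_fp] <- lg$intensity[bi] + eye$b * cfg$biomarker_contrast
    }
  }
  bot_last <- matrix(lg$offset_px[nb] + lg$thickness_px[nb] + shift,
                     H, W, byrow = TRUE)
  img[rowm >= bot_last] <- cfg$sub_rpe_intensity

  if (cfg$speckle_shape > 0) {
    img <- img * matrix(rgamma(H * W, shape = cfg$speckle_shape,
                               rate = cfg$speckle_shape), nrow = H)
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  bscan_image(pixels = img, fovea_col = cfg$fovea_col,
              lateral_scale_mm_per_px = cfg$lateral_scale_mm_per_px,
              axial_scale_mm_per_px = cfg$axial_scale_mm_per_px,
              patient_id = eye$patient_id, eye_id = eye$eye_id,
              volume_id = volume_id,
              b = eye$b, depth_jitter_px = eye$depth_jitter_px)
}

#' Ground-truth biomarker pixel mask
#'
#' Logical image-sized mask marking the pixels of the two hyporeflective
#' biomarker bands (`myoid`, `subez_gap`) inside the lateral footprint, for
#' the given eye's geometry. Used to score occlusion-map localization
#' against the injected ground truth.
#'
#' @inheritParams generate_bscan
#' @param bands band names to include.
#' @param lateral `"footprint"` restricts to the biomarker footprint
#'   columns, `"all"` spans the full width.
#' @return logical matrix `image_height_px x image_width_px`.
#' @export
biomarker_mask <- function(cfg, eye, bands = c("myoid", "subez_gap"),
                           lateral = c("footprint", "all")) {
  lateral <- match.arg(lateral)
  H <- cfg$image_height_px; W <- cfg$image_width_px
  lg <- cfg$layer_geometry
  shift <- band_shift_px(cfg, eye)
  cols <- if (lateral == "footprint") footprint_cols(cfg) else seq_len(W)
  m <- matrix(FALSE, H, W)
  rowm <- matrix(seq_len(H), H, W)
  keep_col <- matrix(seq_len(W) %in% cols, H, W, byrow = TRUE)
  for (bi in which(lg$band %in% bands)) {
    top <- matrix(lg$offset_px[bi] + shift, H, W, byrow = TRUE)
    m[rowm >= top & rowm < top + lg$thickness_px[bi] & keep_col] <- TRUE
  }
  m
}

#' Simulate a phantom cohort
#'
#' Draws one latent biomarker strength per patient (uniform on \[0, 1\] by
#' default), renders `eyes_per_patient` eyes times `volumes_per_eye` B-scans
#' per eye (eyes share the patient's `b`, up to per-eye geometry jitter), and
#' one RIT record per volume through [rit_link()]. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @param n_patients number of patients (>= 1).
#' @param eyes_per_patient 1 or 2 eyes per patient.
#' @param volumes_per_eye B-scans rendered per eye.
#' @param b_sampler function `(n) -> b` in \[0, 1\]; defaults to uniform.
#' @return list with `images` (list of [bscan_image()]) and `records`
#'   (data.frame: patient_id, eye_id, volume_id, rit_minutes, b).
#' @export
sample_cohort <- function(cfg, n_patients, eyes_per_patient = 1L,
                          volumes_per_eye = 1L, b_sampler = NULL) {
  if (n_patients < 1L) rit_stop("ritmap_config_error", "n_patients must be >= 1")
  if (!eyes_per_patient %in% 1:2) {
    rit_stop("ritmap_config_error", "eyes_per_patient must be 1 or 2")
  }
  if (is.null(b_sampler)) b_sampler <- function(n) runif(n)
  set.seed(cfg$seed)
  b_pat <- b_sampler(n_patients)

  images <- list()
  recs <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    for (e in seq_len(eyes_per_patient)) {
      eid <- paste0(pid, "_", c("OD", "OS")[e])
      eye <- eye_params(pid, eid, b = b_pat[p],
                        depth_jitter_px = rnorm(1, 0, cfg$jitter_depth_sd_px))
      for (v in seq_len(volumes_per_eye)) {
        vid <- sprintf("%s_V%d", eid, v)
        k <- k + 1L
        images[[k]] <- generate_bscan(cfg, eye, volume_id = vid)
        recs[[k]] <- data.frame(patient_id = pid, eye_id = eid,
                                volume_id = vid,
                                rit_minutes = rit_link(b_pat[p], cfg),
                                b = b_pat[p], stringsAsFactors = FALSE)
      }
    }
  }
  list(images = images, records = do.call(rbind, recs))
}
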