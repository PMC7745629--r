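#' Occlusion perturbation configuration
#'
#' A `patch_w_px x patch_h_px` occlusion window (default 16 lateral x 6
#' axial) is centered at each evaluated pixel position and filled with the
#' patch's own mean intensity (`fill = "mean"`), zeros, or a random
#' permutation of its own pixels. Patches are cropped at image borders and
#' statistics are computed on the cropped support, in float.
#'
#' `inference_mode = "fixed_window"` keeps the model window frozen at its
#' trained location: occlusions whose patch does not intersect the window
#' footprint cannot change the prediction and are stored as exact zeros.
#' `"sliding_window"` re-centers the window laterally at each occlusion
#' column, yielding a full-width map.
#'
#' @param patch_w_px,patch_h_px occlusion patch size (lateral x axial), px.
#' @param fill `"mean"`, `"zero"` or `"permute"`.
#' @param stride_px occlusion-center grid stride, px.
#' @param inference_mode `"fixed_window"` or `"sliding_window"`.
#' @param permute_seed RNG seed used by the `"permute"` fill.
#' @return list of class `occlusion_config`.
#' @export
occlusion_config <- function(patch_w_px = 16L, patch_h_px = 6L,
                             fill = c("mean", "zero", "permute"),
                             stride_px = 1L,
                             inference_mode = c("fixed_window",
                                                "sliding_window"),
                             permute_seed = 1L) {
  fill <- match.arg(fill)
  inference_mode <- match.arg(inference_mode)
  if (patch_w_px < 1L || patch_h_px < 1L || stride_px < 1L) {
    rit_stop("ritmap_config_error", "patch dims and stride must be >= 1")
  }
  structure(list(patch_w_px = as.integer(patch_w_px),
                 patch_h_px = as.integer(patch_h_px),
                 fill = fill, stride_px = as.integer(stride_px),
                 inference_mode = inference_mode,
                 permute_seed = as.integer(permute_seed)),
            class = "occlusion_config")
}

# Patch extent around a center: height rows [r-floor(h/2), ...], width cols,
# cropped to the matrix. Returns list(rows, cols) of index vectors.
patch_extent <- function(center, cfg, dims) {
  r <- center[1]; ci <- center[2]
  h <- cfg$patch_h_px; w <- cfg$patch_w_px
  r0 <- r - h %/% 2L; r1 <- r0 + h - 1L
  c0 <- ci - w %/% 2L; c1 <- c0 + w - 1L
  list(rows = max(1L, r0):min(dims[1], r1),
       cols = max(1L, c0):min(dims[2], c1))
}

#' Occlude one patch of an image or window
#'
#' @param x numeric/integer matrix (image pixels or a normalized patch) or
#'   a [bscan_image()].
#' @param center `c(row, col)` of the occlusion-patch center (1-based).
#' @param cfg an [occlusion_config()].
#' @return perturbed copy of the pixel matrix (numeric; mean fill is not
#'   re-quantized).
#' @export
occlude_patch <- function(x, center, cfg) {
  px <- if (inherits(x, "bscan_image")) x$pixels else x
  if (center[1] < 1L || center[1] > nrow(px) ||
      center[2] < 1L || center[2] > ncol(px)) {
    rit_stop("ritmap_range_error", "occlusion center (%d, %d) outside image",
             center[1], center[2])
  }
  ext <- patch_extent(center, cfg, dim(px))
  px <- px * 1.0  # numeric copy
  vals <- px[ext$rows, ext$cols]
  px[ext$rows, ext$cols] <- switch(
    cfg$fill,
    mean = mean(vals),
    zero = 0,
    permute = {
      set.seed(cfg$permute_seed)
      matrix(sample(as.numeric(vals)), nrow = length(ext$rows))
    })
  px
}

# Shared bookkeeping: frozen window placement from the unperturbed image.
frozen_placement <- function(image, spec) {
  w <- extract_window(image, spec)
  list(rows = w$rows[1]:w$rows[2], cols = w$cols[1]:w$cols[2], window = w)
}

#' Signed occlusion map over a B-scan
#'
#' Baseline = ensemble RIT prediction on the unperturbed window (placement
#' computed once from the unperturbed image and held fixed for every
#' perturbation, so occlusions cannot move the window). For each occlusion
#' center on the stride grid the patch is filled per `cfg`, the window
#' re-extracted at the frozen placement, and the signed difference
#' `perturbed - baseline` recorded in minutes.
#'
#' @param ensemble a [model_ensemble()] (or single `rit_cnn`).
#' @param image a [bscan_image()].
#' @param spec the [window_spec()] the ensemble was trained with.
#' @param cfg an [occlusion_config()].
#' @param chunk number of perturbed windows per prediction batch.
#' @return object of class `occlusion_map`: `delta_rit_minutes` (matrix
#'   `length(row_centers) x length(col_centers)`), `row_centers`,
#'   `col_centers`, `baseline_rit_minutes`, `evaluated` (logical matrix),
#'   `config`, window placement echo.
#' @export
occlusion_map <- function(ensemble, image, spec, cfg = occlusion_config(),
                          chunk = 256L) {
  if (inherits(ensemble, "rit_cnn")) ensemble <- model_ensemble(list(ensemble))
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  row_centers <- seq(1L, H, by = cfg$stride_px)
  col_centers <- seq(1L, W, by = cfg$stride_px)
  delta <- matrix(0, length(row_centers), length(col_centers))
  evaluated <- matrix(FALSE, length(row_centers), length(col_centers))

  if (cfg$inference_mode == "fixed_window") {
    pl <- frozen_placement(image, spec)
    baseline <- predict_rit(ensemble, pl$window$patch)
    # a center is relevant iff its (uncropped) patch intersects the window
    half_h0 <- cfg$patch_h_px %/% 2L; half_h1 <- cfg$patch_h_px - half_h0 - 1L
    half_w0 <- cfg$patch_w_px %/% 2L; half_w1 <- cfg$patch_w_px - half_w0 - 1L
    rr <- range(pl$rows); cr <- range(pl$cols)
    rel_r <- which(row_centers + half_h1 >= rr[1] & row_centers - half_h0 <= rr[2])
    rel_c <- which(col_centers + half_w1 >= cr[1] & col_centers - half_w0 <= cr[2])
    centers <- expand.grid(ri = rel_r, ci = rel_c)
    base_patch <- pl$window$patch
    npix <- length(base_patch)
    for (s in seq(1L, nrow(centers), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(centers))
      xb <- matrix(0, npix, length(idx))
      for (k in seq_along(idx)) {
        ri <- centers$ri[idx[k]]; ci <- centers$ci[idx[k]]
        pert <- perturb_window_pixels(image, pl,
                                      c(row_centers[ri], col_centers[ci]),
                                      cfg, base_patch)
        xb[, k] <- pert
      }
      preds <- predict_rit(ensemble, xb)
      # identity perturbations (e.g. mean fill over a constant region) are
      # exact zeros by definition, immune to BLAS batching round-off
      unchanged <- colSums(xb != as.numeric(base_patch)) == 0L
      for (k in seq_along(idx)) {
        ri <- centers$ri[idx[k]]; ci <- centers$ci[idx[k]]
        delta[ri, ci] <- if (unchanged[k]) 0 else preds[k] - baseline
        evaluated[ri, ci] <- TRUE
      }
    }
  } else {
    half_w <- spec$width_px %/% 2L
    for (ci in seq_along(col_centers)) {
      cc <- col_centers[ci]
      c0 <- cc - half_w
      if (c0 < 1L || c0 + spec$width_px - 1L > W) next
      sp_c <- window_spec(col_to_eccentricity(cc, image),
                          spec$width_px, spec$height_px)
      pl <- frozen_placement(image, sp_c)
      baseline <- predict_rit(ensemble, pl$window$patch)
      xb <- matrix(0, spec$width_px * spec$height_px, length(row_centers))
      for (ri in seq_along(row_centers)) {
        xb[, ri] <- perturb_window_pixels(image, pl,
                                          c(row_centers[ri], cc), cfg,
                                          pl$window$patch)
      }
      preds <- predict_rit(ensemble, xb)
      unchanged <- colSums(xb != as.numeric(pl$window$patch)) == 0L
      delta[, ci] <- ifelse(unchanged, 0, preds - baseline)
      evaluated[, ci] <- TRUE
    }
    baseline <- NA_real_  # per-column baselines in sliding mode
  }

  structure(list(delta_rit_minutes = delta, row_centers = row_centers,
                 col_centers = col_centers,
                 baseline_rit_minutes = if (cfg$inference_mode ==
                                            "fixed_window") baseline
                                        else NA_real_,
                 evaluated = evaluated, config = cfg,
                 window_rows = if (cfg$inference_mode == "fixed_window")
                   range(frozen_placement(image, spec)$rows) else NULL,
                 volume_id = image$volume_id,
                 image_dims = c(H, W)),
            class = "occlusion_map")
}

# Normalized window pixels after occluding the full image at `center`.
# Only the window footprint is materialized; the fill statistic is computed
# on the patch cropped to the image (which may extend beyond the window).
perturb_window_pixels <- function(image, pl, center, cfg, base_patch) {
  ext <- patch_extent(center, cfg, dim(image$pixels))
  vals <- image$pixels[ext$rows, ext$cols]
  fill_vals <- switch(cfg$fill,
    mean = mean(vals),
    zero = 0,
    permute = {
      set.seed(cfg$permute_seed)
      matrix(sample(as.numeric(vals)), nrow = length(ext$rows))
    })
  patch <- base_patch
  rsel <- intersect(ext$rows, pl$rows)
  csel <- intersect(ext$cols, pl$cols)
  if (length(rsel) && length(csel)) {
    if (is.matrix(fill_vals)) {
      fv <- fill_vals[match(rsel, ext$rows), match(csel, ext$cols),
                      drop = FALSE]
    } else {
      fv <- fill_vals
    }
    patch[match(rsel, pl$rows), match(csel, pl$cols)] <- fv / 255
  }
  as.numeric(patch)
}

#' Naive occlusion-map oracle
#'
#' Independently coded reference: a plain double loop that, for every
#' evaluated grid center, copies the whole image, occludes it with
#' [occlude_patch()], re-extracts the frozen-placement window, and predicts
#' one window at a time. Used to verify the batched [occlusion_map()];
#' orders of magnitude slower.
#'
#' @inheritParams occlusion_map
#' @return `occlusion_map` object (fixed_window mode only).
#' @export
occlusion_map_naive <- function(ensemble, image, spec,
                                cfg = occlusion_config()) {
  if (inherits(ensemble, "rit_cnn")) ensemble <- model_ensemble(list(ensemble))
  stopifnot(cfg$inference_mode == "fixed_window")
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  pl <- frozen_placement(image, spec)
  baseline <- predict_rit(ensemble, pl$window$patch)
  row_centers <- seq(1L, H, by = cfg$stride_px)
  col_centers <- seq(1L, W, by = cfg$stride_px)
  delta <- matrix(0, length(row_centers), length(col_centers))
  evaluated <- matrix(FALSE, length(row_centers), length(col_centers))
  for (ri in seq_along(row_centers)) {
    for (ci in seq_along(col_centers)) {
      ext <- patch_extent(c(row_centers[ri], col_centers[ci]), cfg,
                          c(H, W))
      if (max(ext$rows) < min(pl$rows) || min(ext$rows) > max(pl$rows) ||
          max(ext$cols) < min(pl$cols) || min(ext$cols) > max(pl$cols)) {
        next  # patch disjoint from window: delta exactly 0
      }
      pert <- occlude_patch(image$pixels, c(row_centers[ri],
                                            col_centers[ci]), cfg)
      wpix <- pert[pl$rows, pl$cols] / 255
      delta[ri, ci] <- predict_rit(ensemble, matrix(as.numeric(wpix),
                                                    ncol = 1)) - baseline
      evaluated[ri, ci] <- TRUE
    }
  }
  structure(list(delta_rit_minutes = delta, row_centers = row_centers,
                 col_centers = col_centers, baseline_rit_minutes = baseline,
                 evaluated = evaluated, config = cfg,
                 window_rows = range(pl$rows), volume_id = image$volume_id,
                 image_dims = c(H, W)),
            class = "occlusion_map")
}

#' Robustness of the occlusion map to fill rule and patch size
#'
#' Recomputes maps under the three fill rules at the base patch size and
#' under patch sizes (16, 6), (8, 3), (32, 12) with mean fill, then reports
#' pairwise Spearman correlations of |delta| over the union of evaluated
#' positions, pooled across images. All-zero map pairs are reported as
#' degenerate (`NA` correlation).
#'
#' @param ensemble a [model_ensemble()].
#' @param images list of [bscan_image()].
#' @param spec the [window_spec()] of the ensemble.
#' @param base_cfg base [occlusion_config()].
#' @return list with `variants` (the configs), `correlations` (data.frame
#'   cfg_a, cfg_b, spearman), and `degenerate` flags.
#' @export
sensitivity_suite <- function(ensemble, images, spec,
                              base_cfg = occlusion_config()) {
  if (length(images) == 0L) rit_stop("ritmap_data_error", "need >= 1 image")
  variants <- list()
  for (f in c("mean", "zero", "permute")) {
    variants[[paste0("fill_", f)]] <-
      occlusion_config(base_cfg$patch_w_px, base_cfg$patch_h_px, fill = f,
                       stride_px = base_cfg$stride_px,
                       inference_mode = "fixed_window",
                       permute_seed = base_cfg$permute_seed)
  }
  for (sz in list(c(8L, 3L), c(32L, 12L))) {
    variants[[sprintf("size_%dx%d", sz[1], sz[2])]] <-
      occlusion_config(sz[1], sz[2], fill = "mean",
                       stride_px = base_cfg$stride_px,
                       inference_mode = "fixed_window",
                       permute_seed = base_cfg$permute_seed)
  }
  # all variants share the stride grid, so maps align position-by-position;
  # compare on the union of evaluated positions (unevaluated are exact 0)
  maps <- lapply(variants, function(cf) {
    lapply(images, function(im) occlusion_map(ensemble, im, spec, cf))
  })
  union_eval <- lapply(seq_along(images), function(k) {
    Reduce(`|`, lapply(maps, function(mm) mm[[k]]$evaluated))
  })
  absvals <- lapply(maps, function(mm) {
    unlist(lapply(seq_along(mm), function(k) {
      abs(mm[[k]]$delta_rit_minutes[union_eval[[k]]])
    }))
  })
  nm <- names(variants)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    a <- absvals[[i]]; b <- absvals[[j]]
    degenerate <- sd(a) == 0 || sd(b) == 0
    rho <- if (degenerate) NA_real_ else cor(a, b, method = "spearman")
    rows[[length(rows) + 1L]] <- data.frame(
      cfg_a = nm[i], cfg_b = nm[j], spearman = rho,
      degenerate = degenerate)
  }
  list(variants = variants, correlations = do.call(rbind, rows))
}

#' Render a signed overlay of an occlusion map
#'
#' Grayscale base image with a diverging overlay: positive delta
#' (RIT-lengthening) in red, negative (shortening) in blue, alpha
#' proportional to |delta| scaled by the map's 99th percentile of |delta|.
#' Zero-delta pixels are left unmodified.
#'
#' @param map an `occlusion_map` (stride 1 for pixel-aligned overlays).
#' @param image the source [bscan_image()].
#' @return numeric array `H x W x 3` with values in \[0, 1\].
#' @export
render_overlay <- function(map, image) {
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  delta_full <- matrix(0, H, W)
  delta_full[map$row_centers, map$col_centers] <- map$delta_rit_minutes
  if (!all(dim(delta_full) == c(H, W))) {
    rit_stop("ritmap_shape_error", "map does not align with image grid")
  }
  base <- image$pixels / 255
  rgb <- array(rep(base, 3), dim = c(H, W, 3))
  nz <- abs(delta_full[delta_full != 0])
  if (length(nz) == 0) return(rgb)
  mx <- quantile(nz, 0.99, names = FALSE)
  if (is.na(mx) || mx == 0) return(rgb)
  alpha <- pmin(abs(delta_full) / mx, 1)
  pos <- delta_full > 0; neg <- delta_full < 0
  # blend toward pure red / blue with weight alpha
  rgb[, , 1][pos] <- (1 - alpha[pos]) * base[pos] + alpha[pos]
  rgb[, , 2][pos] <- (1 - alpha[pos]) * base[pos]
  rgb[, , 3][pos] <- (1 - alpha[pos]) * base[pos]
  rgb[, , 1][neg] <- (1 - alpha[neg]) * base[neg]
  rgb[, , 2][neg] <- (1 - alpha[neg]) * base[neg]
  rgb[, , 3][neg] <- (1 - alpha[neg]) * base[neg] + alpha[neg]
  rgb
}

#' Replace band pixels with those of a donor image
#'
#' Counterfactual probe: substitute the biomarker-band pixels of one
#' phantom with the corresponding pixels of another (e.g. a `b = 0` render
#' of the same eye) and keep everything else untouched.
#'
#' @param image,donor two [bscan_image()] of identical dimensions.
#' @param mask logical matrix from [biomarker_mask()].
#' @return `bscan_image` copy of `image` with masked pixels from `donor`.
#' @export
swap_band_pixels <- function(image, donor, mask) {
  if (!all(dim(image$pixels) == dim(donor$pixels)) ||
      !all(dim(mask) == dim(image$pixels))) {
    rit_stop("ritmap_shape_error", "image, donor and mask dims must match")
  }
  out <- image
  out$pixels[mask] <- donor$pixels[mask]
  out
}

#' Write an occlusion map as CSV
#' @param map an `occlusion_map`.
#' @param path CSV destination (columns row, col, delta_rit_minutes), one
#'   line per evaluated position.
#' @export
write_map_csv <- function(map, path) {
  ev <- which(map$evaluated, arr.ind = TRUE)
  write.csv(data.frame(row = map$row_centers[ev[, 1]],
                       col = map$col_centers[ev[, 2]],
                       delta_rit_minutes = map$delta_rit_minutes[ev]),
            path, row.names = FALSE)
  invisible(path)
}
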