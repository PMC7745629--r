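#' Train per-location ensembles across an eccentricity grid
#'
#' For each grid location: extract the window dataset, run
#' `cfg$n_repetitions` training sessions, evaluate every session-best model
#' on the validation split (in minutes), and aggregate into a location
#' result with normal-approximation 95% confidence intervals across
#' repetitions (`mean +- 1.96 sd / sqrt(n)`). The test split is never
#' touched here; it is reserved for occlusion mapping and final metrics.
#'
#' Locations where window extraction fails for any image are dropped with a
#' warning rather than silently skipped.
#'
#' @param cohort list with `images` and `records` from [sample_cohort()].
#' @param grid numeric vector of signed eccentricities, mm.
#' @param cfg a [train_config()].
#' @param split named split vector from [split_cohort()].
#' @param keep_ensembles keep each location's [model_ensemble()] (memory
#'   permitting) so the best-location ensemble can be reused directly.
#' @return object of class `eccentricity_curve`: data.frame `curve` (columns
#'   eccentricity_mm, mean_rmse_min, mean_mae_min, ci_rmse, ci_mae,
#'   n_repetitions), list `locations` of per-location detail, `argmin_mm`,
#'   and optionally `ensembles`.
#' @export
sweep_eccentricities <- function(cohort, grid, cfg, split,
                                 keep_ensembles = TRUE) {
  if (length(grid) == 0L) rit_stop("ritmap_config_error", "empty grid")
  grid <- sort(grid)
  locations <- list()
  ensembles <- list()
  for (ecc in grid) {
    ds <- tryCatch(
      build_window_dataset(cohort, ecc, split = split,
                           width_px = cfg$width_px,
                           height_px = cfg$height_px),
      error = function(e) e)
    if (inherits(ds, "error")) {
      warning(sprintf("dropping location %+.2f mm: %s", ecc,
                      conditionMessage(ds)))
      next
    }
    tr <- subset_windows(ds, ds$manifest$split == "train")
    va <- subset_windows(ds, ds$manifest$split == "val")
    ens <- run_repetitions(tr, va, cfg, eccentricity_mm = ecc)
    per_rep <- lapply(ens$sessions, function(s) {
      p <- predict_rit(s$model, va$x)
      evaluate(p, va$manifest$rit_minutes)
    })
    rmse <- vapply(per_rep, `[[`, numeric(1), "rmse")
    mae <- vapply(per_rep, `[[`, numeric(1), "mae")
    n <- length(rmse)
    ci <- function(v) if (n > 1L) 1.96 * sd(v) / sqrt(n) else 0
    locations[[length(locations) + 1L]] <- list(
      eccentricity_mm = ecc, rmse_min = rmse, mae_min = mae,
      mean_rmse_min = mean(rmse), mean_mae_min = mean(mae),
      ci_rmse = ci(rmse), ci_mae = ci(mae), n_repetitions = n)
    if (keep_ensembles) ensembles[[as.character(ecc)]] <- ens
  }
  if (length(locations) == 0L) {
    rit_stop("ritmap_data_error", "no grid location admitted a full window")
  }
  curve <- do.call(rbind, lapply(locations, function(l) {
    data.frame(eccentricity_mm = l$eccentricity_mm,
               mean_rmse_min = l$mean_rmse_min,
               mean_mae_min = l$mean_mae_min,
               ci_rmse = l$ci_rmse, ci_mae = l$ci_mae,
               n_repetitions = l$n_repetitions)
  }))
  out <- structure(list(curve = curve, locations = locations,
                        argmin_mm = NA_real_,
                        ensembles = if (keep_ensembles) ensembles else NULL),
                   class = "eccentricity_curve")
  out$argmin_mm <- best_location(out)
  out
}

#' Location of minimum mean validation RMSE
#'
#' Ties break toward smaller absolute eccentricity, then toward the
#' negative (temporal) sign; the rule is arbitrary but fixed.
#'
#' @param curve an `eccentricity_curve` (or its `curve` data.frame).
#' @return eccentricity in mm.
#' @export
best_location <- function(curve) {
  cv <- if (inherits(curve, "eccentricity_curve")) curve$curve else curve
  if (is.null(cv) || nrow(cv) == 0L) {
    rit_stop("ritmap_data_error", "empty eccentricity curve")
  }
  cand <- cv$eccentricity_mm[cv$mean_rmse_min == min(cv$mean_rmse_min)]
  cand[order(abs(cand), cand)][1]
}

#' @export
print.eccentricity_curve <- function(x, ...) {
  cat(sprintf("<eccentricity_curve: %d locations, argmin %+.2f mm>\n",
              nrow(x$curve), x$argmin_mm))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Write the curve as CSV
#' @param curve an `eccentricity_curve`.
#' @param path destination CSV.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}

#' Plot the eccentricity-error curve
#'
#' Mean validation RMSE per location with the 95% CI band across training
#' repetitions, and the per-location best session overlaid.
#'
#' @param curve an `eccentricity_curve`.
#' @param path optional PNG destination; when `NULL` plots to the active
#'   device.
#' @export
plot_curve <- function(curve, path = NULL) {
  cv <- curve$curve
  if (!is.null(path)) grDevices::png(path, width = 720, height = 480)
  best <- vapply(curve$locations, function(l) min(l$rmse_min), numeric(1))
  ylim <- range(cv$mean_rmse_min - cv$ci_rmse, cv$mean_rmse_min + cv$ci_rmse,
                best)
  plot(cv$eccentricity_mm, cv$mean_rmse_min, type = "n", ylim = ylim,
       xlab = "eccentricity from fovea (mm, nasal positive)",
       ylab = "validation RMSE (min)",
       main = "RIT prediction error by anatomic location")
  graphics::polygon(c(cv$eccentricity_mm, rev(cv$eccentricity_mm)),
                    c(cv$mean_rmse_min + cv$ci_rmse,
                      rev(cv$mean_rmse_min - cv$ci_rmse)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(cv$eccentricity_mm, cv$mean_rmse_min, col = "steelblue",
                  lwd = 2)
  graphics::points(cv$eccentricity_mm, best, pch = 4, col = "grey40")
  graphics::abline(v = curve$argmin_mm, lty = 2, col = "firebrick")
  if (!is.null(path)) grDevices::dev.off()
  invisible(curve)
}
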