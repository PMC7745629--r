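# ritmap

Anatomically restricted CNN regression and occlusion mapping for retinal
OCT biomarker discovery.

## What problem this solves

Rod-mediated dark adaptation slows early in age-related macular
degeneration; its readout, the **rod intercept time** (RIT, minutes), is a
functional biomarker measured psychophysically. `ritmap` is for
researchers who want to ask the inverse question of structural imaging:
*where on an OCT B-scan, and in which reflectivity bands, does the image
predict RIT?* The package implements a complete localization pipeline:

1. **Phantom cohorts** — layered-retina B-scan simulation (ELM, myoid
   zone, EZ, EZ–IZ hyporeflective gap, IZ, RPE-BrM, Gaussian foveal pit,
   multiplicative gamma speckle) with a known injected biomarker: the two
   hyporeflective bands flanking the EZ brighten with latent severity
   `b ∈ [0, 1]`, and RIT is affine in `b` plus noise
   (`RIT = 5 + 35·b + ε` minutes, normalized by the 40-minute ceiling).
2. **Registration** — 64×256 px windows centered on a signed eccentricity
   (mm from the fovea, nasal positive), vertically placed on the pooled
   horizontal maximum-intensity-projection row; patient-level 60/20/20
   train/val/test splits.
3. **Regression** — small CNNs (stride-2 3×3 conv blocks → flatten →
   dense → linear head) trained with Nadam on MSE of RIT/40 against
   inputs/255, Xavier-normal init, per-session best-validation-epoch
   weights, repeated sessions ensembled by averaging; prediction is
   40× the mean normalized output.
4. **Localization** — per-eccentricity validation RMSE/MAE curves with
   95% CIs across repetitions; the argmin is the discovered location.
5. **Attribution** — signed mean-occlusion maps: a 16×6 px patch is
   replaced by its own mean at every grid position and the change in
   predicted RIT (minutes) recorded; red = RIT-lengthening,
   blue = shortening in rendered overlays; permuted/zero fills and other
   patch sizes as sensitivity checks; an independently coded per-pixel
   oracle verifies the batched implementation.

Two training profiles are built in: `paper_faithful` (lr 2e-4, batch 26,
600 epochs, 9 repetitions) reproducing the published protocol, and `desk`
(30 epochs, 3 repetitions, small CNN, lr 5e-3) for single-CPU use. The
CNN itself — forward, backward, Nadam — is implemented in
RcppArmadillo; no deep-learning framework is required.

## Worked example

```r
library(ritmap)

cfg <- phantom_config(seed = 42)        # biomarker at +0.3 mm, width 0.5 mm
cohort <- sample_cohort(cfg, n_patients = 200)
split <- split_cohort(cohort$records, seed = 42)

tc <- train_config("desk")
curve <- sweep_eccentricities(cohort, seq(-1.5, 1.5, by = 0.25), tc, split)
print(curve)

ens <- curve$ensembles[[as.character(curve$argmin_mm)]]
ds  <- build_window_dataset(cohort, curve$argmin_mm, split = split)
test <- ds$manifest$split == "test"
metrics <- evaluate(predict_rit(ens, ds$x[, test]),
                    ds$manifest$rit_minutes[test])
cat(sprintf("test RMSE %.2f min, MAE %.2f min, Pearson %.2f\n",
            metrics$rmse, metrics$mae, metrics$pearson))
```

On this seed the sweep prints (validation RMSE in minutes; ~2.5 min on one
CPU):

```
<eccentricity_curve: 13 locations, argmin +0.50 mm>
 eccentricity_mm mean_rmse_min mean_mae_min    ci_rmse     ci_mae n_repetitions
           -1.50     10.153995     8.676215 0.07686835 0.13741604             3
           -1.25     10.232389     8.634458 0.01456635 0.07027130             3
           -1.00     10.089956     8.692448 0.12452928 0.22336281             3
           -0.75      9.771292     8.188201 0.06133676 0.38453041             3
           -0.50     10.101278     8.538456 0.09867743 0.08122204             3
           -0.25      3.918634     3.293834 1.00432654 0.89515575             3
            0.00      3.616223     2.938731 0.45894267 0.35854665             3
            0.25      3.460935     2.779305 1.25546346 0.99129190             3
            0.50      2.604322     2.120188 0.33936328 0.26942997             3
            0.75      4.283094     3.181582 0.97893286 0.84176344             3
            1.00      5.775334     4.661771 1.81005678 1.55118075             3
            1.25     10.041655     8.480474 0.25470737 0.28816760             3
            1.50      9.610182     8.011411 0.04250046 0.17705057             3
test RMSE 1.72 min, MAE 1.43 min, Pearson 0.99
```

Reading it: the error collapses from ~10 min (the label SD — windows with
no biomarker content) to ~3 min exactly where the 64-px (0.96 mm) window
overlaps the injected footprint (+0.05 to +0.55 mm), and the argmin +0.50
localizes the biomarker to within one 0.25 mm grid step of its +0.3 mm
center. Test-set predictions at that location recover the underlying
severity signal (r = 0.99 against truth whose noise floor is 1 min).
Occlusion maps then pinpoint the responsible pixels:

```r
im   <- cohort$images[[which(test)[1]]]
spec <- window_spec(curve$argmin_mm)
m    <- occlusion_map(ens, im, spec, occlusion_config(stride_px = 2))
write_ppm(render_overlay(m, im), "overlay.ppm")
```

The largest |ΔRIT| positions concentrate in the myoid zone and the EZ–IZ
gap inside the footprint — the bands the generator actually perturbed.

## Command line

```sh
Rscript -e 'ritmap::ritmap_main()' run-all --config cfg.json --seed 1
# subcommands: simulate | split | train | sweep | occlude | report | run-all
```

All outputs (PGM images, labels.csv, curve CSV/PNG, occlusion CSVs, PPM
overlays, Markdown report, JSON manifests) land in one run directory.

## Documentation

`vignettes/ritmap-methods.Rmd` describes the model, the phantom's stated
world and its limits, every tunable parameter with units and defaults,
and the design decisions (flatten vs GAP, speckle shape, desk learning
rate, tie-break and rounding rules).
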