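# evkit

Single-molecule imaging analysis of small extracellular vesicles (sEVs).

Small extracellular vesicles (~50–150 nm membrane vesicles carrying
tetraspanin markers CD9, CD63, CD81) are internalized by recipient cells
through membrane invaginations such as caveolae and clathrin-independent
endocytic domains. Studying that process with single-molecule localization
microscopy requires a chain of specialised computations, and this package
implements that chain as tested, reusable R functions for researchers
analysing PALM/dSTORM localization tables and two-color single-vesicle
images:

* **PALM movies** — pseudo-real-time super-resolution reconstructions from
  rolling windows over a localization table. Each spot contributes a
  Gaussian kernel
  *p<sub>i</sub>(x,y) = exp(−((x−x<sub>i</sub>)² + (y−y<sub>i</sub>)²) /
  2(Au<sub>i</sub>)²) / 2π(Au<sub>i</sub>)²* with SD proportional
  (A = 6) to its localization uncertainty u<sub>i</sub>; windows of
  W = 1002 frames advance in steps of 6 (a 5008-frame acquisition yields
  669 reconstructions).
* **Segmentation** — Otsu thresholding of the probability images (exact
  minimization of the mean intraclass variance), minimum cross-entropy
  ("Li") thresholding for two-color particle images, marching-squares
  sub-pixel contours, and Voronoi polygon-density object detection
  (density factor 5 over the dataset mean, ≥ 100 localizations per
  object) with vesicle diameter estimation.
* **Colocalization** — signed contour-distance profiles (negative inside
  the structure, 50 nm bins, normalized by uniform random controls) with
  an enrichment score over [−200, 0] nm; pair cross-correlation C(r)
  against a 180°-rotated control; residence-event frequencies in
  events/µm²/min; and Li-binarized two-color particle overlap counts
  (M/R ratios).
* **Stoichiometry** — log-normal monomer calibration, non-negative
  least-squares decomposition of single-vesicle intensity histograms into
  1–10-mer components, the Poisson detection fraction 1 − e<sup>−λ</sup>,
  and inference of sEV subtype mixtures (weights over the 7 subsets of
  {CD9, CD63, CD81}) from pairwise two-color colocalization tables.
* **Synthetic data** — seeded generators for every input class (blinking
  clustered fields, spherical-shell vesicle clouds, zero-truncated-Poisson
  copy numbers with log-normal monomer intensities, two-color subtype
  populations), so the whole pipeline is testable without microscope data.

See the methods vignette (`vignettes/ev-imaging-methods.Rmd`) for the
models, parameter meanings and design decisions.

## Worked example

```r
library(evkit)

## Size simulated 111-nm liposomes through the Voronoi pipeline
sim <- simulate_vesicle_field(20, field = roi(6400, 6400),
                              true_diameter = 111,
                              n_localizations = c(150, 300),
                              precision = 20, seed = 42)
objs <- voronoi_objects(sim$table, density_factor = 5,
                        min_localizations = 100, roi = sim$field)
d <- vapply(objs, object_diameter, numeric(1))
sprintf("%d vesicles; mean diameter %.1f +/- %.1f nm", length(objs), mean(d), sd(d))
#> "20 vesicles; mean diameter 102.0 +/- 3.3 nm"

## Copy-number stoichiometry of a labeled vesicle population
mono <- fit_monomer_lognormal(sample_vesicle_intensities(
  population_spec(lambda_copies = 1e-9, n_vesicles = 5000, seed = 1))$intensity)
pop <- sample_vesicle_intensities(population_spec(lambda_copies = 4.5,
                                                  n_vesicles = 5000, seed = 2))
fit <- fit_intensity_mixture(pop$intensity, mono, mode = "convolution")
c(lambda = fit$lambda, detect = poisson_detect_fraction(fit$lambda))
#>    lambda    detect
#> 4.5627636 0.9895668

## Segment a clustered field and measure particle enrichment
fs <- field_spec(roi_width = 4000, roi_height = 4000, n_frames = 1002,
                 cluster_centers = cbind(c(1000, 2800, 2000),
                                         c(1200, 1000, 3000)),
                 cluster_radius = 150, cluster_rate = 0.3,
                 background_rate = 0.05, seed = 3)
img <- kde_image(generate_localization_field(fs), kde_params(), roi(4000, 4000))
seg <- otsu_threshold(img)
seg
#> <otsu_result> threshold 4.275e-07; in: 4824 px (mu 8.151e-07), out: 155176 px (mu 3.75e-08)
```

The sizing readout (~102 nm for 111-nm shells at 20 nm precision) matches
the reference-liposome calibration of the pipeline; the fitted copy number
(~4.6 per vesicle) implies that ~99% of marker-carrying vesicles are
detected, and the Otsu segmentation isolates the 3% of the field occupied
by the simulated membrane domains. Placing particles inside those domains
and running `distance_profile()` + `enrichment_score()` returns an
enrichment of ~58 over the [−200, 0] nm band (chance level is 1).

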