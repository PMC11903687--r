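---
title: "Models and methods behind evkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evkit)
```

evkit implements the image-analysis computations used to study how single
small extracellular vesicles (sEVs) interact with recipient-cell plasma
membranes in single-molecule localization microscopy (SMLM) experiments:
pseudo-real-time PALM reconstruction of membrane invaginations, their
segmentation, two colocalization statistics for sEV particles against those
structures, Voronoi-density sizing of vesicles imaged by dSTORM, and
fluorophore-stoichiometry / subtype inference from single-vesicle intensity
data.  This vignette records the models, the tunable parameters, and the
design choices where the method definitions left genuine freedom.

## Rolling-window KDE reconstruction

A localization table holds, per detected fluorophore, the frame index,
fitted coordinates $(x_i, y_i)$ in nm and the localization uncertainty
$u_i$ in nm (the standard error of the fitted position).  Each spot
contributes a Gaussian *existence probability*

$$p_i(x, y) = \frac{1}{2 \pi (A u_i)^2}
  \exp\left(-\frac{(x - x_i)^2 + (y - y_i)^2}{2 (A u_i)^2}\right),$$

and a reconstruction is the average $p(x, y) = \alpha \frac{1}{N} \sum_i
p_i + (1 - \alpha) p_{bg}$ sampled at pixel centres.

* `A` (default 6) converts an uncertainty into a kernel SD.  It is an
  instrument calibration, not a free smoothing parameter.
* `pixel_size` defaults to 10 nm, the working resolution of the
  reconstructions.
* `alpha` defaults to 1: the background mixture term exists in the model
  but no published values for $\alpha, \mu_{bg}, \sigma_{bg}$ are
  available, so background is off unless configured.  When enabled, the
  background is i.i.d. Gaussian per pixel (clipped at zero), seeded
  explicitly.
* Spots with uncertainties outside `[u_min, u_max]` (defaults 2 and 60 nm)
  are discarded as physically implausible for a single fluorophore; the
  defaults bracket the ~20 nm precision of the acquisitions the package
  emulates and are configurable.
* Kernels are truncated at 4 SD; the neglected mass ($<3.4\times10^{-4}$)
  is far below the 1% integration tolerance asserted in the tests.

Movies use windows $[st + 1,\, st + W]$ with $W = 1002$ frames and step
$s = 6$.  For a 5008-frame acquisition, strict full windows give 668
reconstructions while the acquisition is described as producing 669; the
669th can only be a final truncated window.  `window_schedule()` therefore
defaults to `include_partial = TRUE`, emitting one truncated window when
frames remain past the last full window and no full window already ends at
the final frame, and reports the discrepancy via `message()` when partial
windows are disabled.  Movie frames store the *average* of the kernels
(rather than their sum); the two conventions differ by the constant $N$,
and the downstream Otsu threshold is scale-invariant, so segmentation is
unaffected.

The matched particle channel, recorded at the same 200 frames/s, is
converted to the movie frame rate by `rolling_average()`, the mean of
non-overlapping 6-frame blocks (200 Hz to 33.3 frames/s).

## Segmentation

**Otsu.**  A reconstruction is binarized at the threshold minimizing the
count-weighted average of the intraclass variances
$\sigma^2[S_{in}, S_{out}] = (N_{in}\sigma^2[S_{in}] +
N_{out}\sigma^2[S_{out}]) / (N_{in} + N_{out})$ with $S_{in} = \{p \ge
\theta\}$.  Candidates are the interior edges of a 256-bin histogram (the
criterion defines the objective, not the discretization; 256 is the
conventional 8-bit grid) but class statistics are computed exactly from
the pixel values at each candidate, so the result agrees with exhaustive
minimization over all distinct values — a property test asserts exactly
that.  Constant images are an explicit error, never a silent empty mask.

**Li.**  Two-color particle counting binarizes each channel at the
minimum cross-entropy ("Li") threshold.  The classical route to that
threshold is a fixed-point iteration from the image mean; on clean bimodal
images it converges to the criterion minimum, but on unstructured images
it can stall in a local minimum.  Because the defining object is the
criterion minimum (and the test suite holds the implementation to an
exhaustive oracle), `li_threshold()` minimizes the cross-entropy exactly
over a 256-bin candidate grid by default and offers
`method = "iterative"` for the classical scheme.  Note that the criterion
is piecewise constant, so on plateaus (no data between two candidate
thresholds) any threshold in the gap yields the identical mask; oracle
comparisons are therefore made on the achieved criterion or mask, not the
raw threshold value.

**Contours.**  Masks are converted to closed polygons by marching squares
at level 0.5 on a background-padded mask, giving sub-pixel boundaries
through pixel-edge midpoints.  Saddle cells are split (diagonally opposite
corners stay disconnected), a fixed convention.  Rings that enclose
foreground are oriented counterclockwise, holes clockwise, established by
even-odd containment depth.

## Voronoi-density vesicle sizing

Localizations are tessellated (Dirichlet/Voronoi, cells clipped to the
rectangular ROI), each localization gets the polygon density $\delta_i =
1/\text{area}_i$, and object seeds are localizations with $\delta_i \ge
f \cdot \bar\delta$ where $\bar\delta$ is the *whole-dataset* mean density
(total count / ROI area) and $f = 5$ is the density factor.  Objects are
connected components of seed cells sharing a Voronoi edge; objects with
fewer than 100 members are discarded, and the boundary is strict (a
99-member object is dropped at the default minimum).  No blink-merging is
applied before tessellation, deliberately matching an analysis pipeline
that counts raw localizations.  Border-touching objects are flagged.

**Diameter.**  Four estimators are available.  The default, `"shell"`,
inverts the imaging model of a surface-labeled vesicle: for fluorophores
uniform on a sphere of radius $R$, the orthographic projection satisfies
$E[r^2] = \tfrac{2}{3} R^2$, and isotropic localization noise of SD
$\sigma$ adds $2\sigma^2$, hence

$$\hat d = 2 \sqrt{\tfrac{3}{2}\left(\overline{r^2} - 2 \bar u^2\right)},$$

with $\overline{r^2}$ the mean squared member distance from the object
centroid and $\bar u$ the members' mean localization uncertainty.  The
alternatives — `"area"` (area-equivalent circle over the clipped-cell
union), `"rms"` ($2\sqrt{2}\,\times$ RMS radius, exact for a uniform disk)
and `"feret"` — are retained, but all three are inflated by the
localization-noise skirt around a shell-shaped cloud: in the reference
simulation below they read roughly 150–180, 150 and 190 nm respectively
for a 111 nm vesicle at 20 nm precision, whereas the shell estimator
reads 100–104 nm.  The anchor for this choice is the reference-liposome
experiment: liposomes of 111 ± 21 nm nanopulse diameter imaged by dSTORM
and sized through this pipeline should read ~110 nm, and only the shell
estimator does.  Its remaining ~7% downward bias comes from the density
threshold truncating the outermost members of each cloud, which lowers
$\overline{r^2}$; we accept it rather than add a truncation correction
that would depend on the (unknown in real data) background level.

The simulated sizing study uses conditions chosen once, on realism
grounds: fields of 6.4 × 6.4 µm with 20 vesicles (~0.5 vesicles/µm²,
a typical surface density for single-particle imaging), 150–300
localizations per vesicle (above the 100-localization analysis cutoff),
and 100 nonspecific background localizations per µm² accumulated over the
acquisition (0.01 µm⁻² per frame over 10,000 frames).

## Colocalization statistics

**Signed contour distance.**  For each particle position, the Euclidean
distance to the nearest segmented-structure contour, negative when the
particle sits inside the structure (mask true at the containing pixel).
Distances are pooled over movie frames and binned at 50 nm.  The control
is the same measurement for spatially uniform random spots against the
same per-frame masks: either Monte-Carlo (default $10^5$ spots pooled
across frames, seeded) or an "analytic" mode that evaluates every pixel
centre of the frame grid — an exact area-weighted quadrature of the
uniform distribution at pixel resolution, which is what the tests use
because it is deterministic.  The normalized profile is the ratio of
relative frequencies; bins with an empty control are flagged `NA`, never
silently dropped.  Frames whose mask is empty contribute neither observed
nor control distances (the statistic is conditional on a structure being
present).  The enrichment score is the mean ratio over the bins fully
inside $[-200, 0]$ nm, i.e. just inside the boundary; 1 means
chance-level association, and for particles confined to structures
covering a fraction $a$ of the field it approaches $1/a$.

**Pair cross-correlation.**  All green–red pairwise distances per frame,
pooled, binned (default 50 nm), divided by the same quantity after
rotating the green channel 180° about the ROI centre.  Rotated points
leaving the ROI are wrapped torus-style, preserving the point count and
density; a discard mode is available.  For independent channels
$C(r) = 1$; for channels paired at ~20 nm jitter the first bin exceeds
the long-range plateau several-fold.

**Event statistics.**  A colocalization event is a maximal run of at
least `min_frames` (default 1) consecutive frames in which a track's
position lies inside the structure mask; point-in-mask uses the track
centroid with no capture radius by default (an sEV radius is 35–55 nm,
comparable to one reconstruction pixel; a capture radius can be
configured).  Frequencies are reported per µm² per minute.

**Two-color particle counting.**  Each channel is Li-binarized,
connected components of at least `min_area_px` pixels (default 4, which
suppresses single-pixel noise) are particles, and M counts the components
of the AND image.  M/R is reported, optionally rescaled by a same-marker
positive control so the control reads 100%; rescaled values above 100%
are reported as-is.

## Stoichiometry and subtype inference

**Monomer calibration.**  Single-fluorophore intensities on glass are fit
by maximum likelihood as a log-normal (mean/SD of log intensities), with a
Kolmogorov–Smirnov distance reported as a goodness-of-fit summary.

**Oligomer mixture.**  Single-vesicle intensity histograms
(Freedman–Diaconis bin width) are decomposed into monomer through 10-mer
components.  The default component model shifts the monomer log-normal by
$\ln n$ in log space (same log-SD) — the standard construction in
stepwise-photobleaching stoichiometry; the exact $n$-fold convolution of
the monomer density is available as `mode = "convolution"` and is the
matched model when the data really are sums of independent monomer draws,
as the synthetic generator produces.  Weights are non-negative least
squares of expected against observed bin counts with Poisson
($1/\sqrt{\text{count}}$) weights.  Components with more than half of
their probability mass beyond the observed intensity range are excluded
as unidentifiable — a vesicle class living there would have produced
observations there — which prevents the fit from inflating raw weights of
far-tail components.  The mean copy number is $\lambda = \sum_n n \pi_n$,
which always lies in $[1, n_{max}]$.

**Detection fraction.**  With copies per vesicle Poisson-distributed, the
fraction of vesicles carrying at least one label is $1 - e^{-\lambda}$;
at $\lambda$ = 4.2–4.8 this is 98.5–99.2%, the quantitative basis for
treating detected particles as essentially all marker-positive vesicles.
Copy numbers in the generator are zero-truncated Poisson because only
labeled vesicles appear in intensity histograms conditioned on detection.

**Subtype mixtures.**  A subtype is a subset of {CD9, CD63, CD81}; the
forward model predicts the percentage of red-detected (Halo) marker-B
particles that are also green-detected (mGFP) for marker A as
$100\, d_G \sum_{S \supseteq \{A,B\}} w_S / \sum_{S \ni B} w_S$ with
independent per-channel detection.  Under the diagonal normalization used
for measured tables (same-marker entries scaled to 100%), the detection
probabilities cancel, so the inverse problem depends only on the weights.
The six off-diagonal constraints are linear and homogeneous in $w$, and
the fit solves them by non-negative least squares on the simplex.  Six
constraints cannot always pin down six free weights, so all weight
supports are scanned in order of size and the sparsest support within 1%
of the optimal residual is returned, with ties flagged as non-unique —
mirroring how sparse (two-subtype) solutions are read off such tables in
practice.  On noise-free tables the forward/inverse round trip is exact
to numerical precision.

Whether measured intensity histograms are conditioned on detection in the
*other* channel is not constrained by the pipeline; the generator exposes
both views (per-channel detection flags are returned per vesicle), and
the stoichiometry fit itself is agnostic.

## The synthetic generator, and what passing tests mean

The generators reproduce the statistical structure the analysis assumes:
Poisson blinking counts in circular nanodomains over uniform background
with truncated-normal per-spot uncertainties (floored at 1 nm to avoid
degenerate kernels); spherical-shell vesicle clouds (membrane proteins
sit on the surface, and on glass the whole shell is within the evanescent
field, so no axial weighting); zero-truncated Poisson copy numbers with
log-normal monomer intensities (defaults: monomer median ~164 photons,
log-SD 0.4, λ = 4.5); and subtype mixtures with independent two-color
detection.  Each generator call takes one explicit seed and restores the
global RNG state.

They deliberately omit photophysics (blinking kinetics, photobleaching
trajectories, multi-frame ON events), camera noise models, drift, and 3D
PSF structure.  Passing recovery tests therefore demonstrates that the
*computations* are correct and internally calibrated — not that the
pipeline is robust to blinking-induced overcounting or drift in real
data, which the upstream localization software is expected to handle.

## Numerical choices and problem sizes

Tests run on reduced but honest problem sizes: ~200 simulated vesicles
for the sizing study, 20 seeded populations of 5000 vesicles for
copy-number recovery, $2\times10^4$–$4\times10^6$ point pairs for the
null calibrations of the colocalization statistics, and 200 random small
images for the thresholding oracles.  Degenerate inputs fail loudly:
constant images, empty masks, empty point sets, all-filtered localization
tables, non-simplex weights, and collinear tessellation inputs all raise
errors with context.  Exact duplicate localizations are separated by a
sub-nanometre jitter before tessellation (Voronoi cells are undefined
otherwise); at 20 nm precision this is far below any measured quantity.

## Known limitations

* The Voronoi mean density is computed over the whole ROI; analyses that
  crop tightly around structures will shift the seed threshold.
* The shell diameter estimator assumes surface labeling; for
  volume-labeled objects the `"rms"` or `"area"` estimators are the
  appropriate choices.
* The greedy tracker has no gap closing and resolves crossing
  trajectories only when nearest-neighbour assignment is unambiguous;
  every analysis here consumes positions, not kinetics.
* Event statistics assume masks and tracks share a frame clock; no
  interpolation between mask frames is attempted.
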