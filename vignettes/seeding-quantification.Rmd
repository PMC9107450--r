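---
title: "Quantifying alpha-synuclein seeding: models, parameters and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alpha-synuclein seeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedQuant)
```

seedQuant quantifies four data types that together characterize
α-synuclein (α-SYN) seeding activity in brain-cohort studies: RT-QuIC
kinetic curves, two-channel fluorescence micrographs, per-case cohort
tables, and size-exclusion chromatography (SEC) elution profiles. This
vignette explains the underlying models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data tests do
and do not establish about real data.

## RT-QuIC kinetic scoring

RT-QuIC amplifies trace amounts of misfolded α-SYN by cyclic
shaking/incubation of recombinant monomer; thioflavin-T (ThT) fluorescence
reports β-sheet aggregate formation. A plate reader records each well
every 30 min for 60 h (120 cycles), and three statistics summarize a well:

* **Threshold**: mean of the pooled first-10-cycle readings of *all* wells
  on the plate plus 25 sample standard deviations of that same pool
  (`computeThreshold()`, `nBaseline = 10`, `kSD = 25`). Pooling across
  wells (rather than per-well thresholds) follows from the threshold being
  defined for all samples at once; one threshold is produced per plate,
  and multi-plate runs get one per plate (batch). The sample
  (n−1) SD estimator is used. A zero-variance pool is legal and gives
  threshold = mean.
* **PAR** (protein aggregation rate): the reciprocal of the time to cross
  the threshold, in h⁻¹. Crossing is the earliest *grid* time with
  F ≥ threshold — no interpolation by default, because the 30-min cycle is
  the assay's native resolution (an `interpolate` flag refines the time
  linearly between the bracketing cycles if wanted). Non-crossing wells
  get PAR = 0 rather than missing, so negatives enter group averages at
  zero rate; `negativePAR = "exclude"` switches to dropping them.
* **MaxFL**: the arithmetic mean of the last 10 cycles, an amplitude
  (plateau) statistic.

A well already at or above threshold at the first cycle cannot have a
meaningful crossing time; it is flagged `invalid_baseline` and excluded
from sample aggregation with a warning. Replicate wells (triplicate by
default for brain lysates) are averaged arithmetically; a biological
sample is called positive when at least half of its valid replicates
crossed (a tie at exactly half counts positive). Reproducibility is
summarized as CV% = 100·SD/mean, intra-batch over replicate wells and
inter-batch over per-plate sample means; CV is undefined (NA with a
warning) at mean zero, which is why near-zero negative controls show
inflated CVs.

Scoring is scale-equivariant: multiplying all readings by c > 0 scales the
threshold and MaxFL by c and leaves crossing times, PAR and positivity
unchanged — so arbitrary fluorescence units are harmless.

### The curve generator

`simulateCurve()` uses a four-parameter logistic,
F(t) = baseline + amplitude·logistic(k(t − t₅₀)) + ε, ε ~ N(0, noiseSd²).
The logistic is a modelling convenience, not a claim about ThT kinetics:
its two shape parameters map directly onto the two reported statistics
(t₅₀ onto lag/crossing, amplitude onto plateau), and
`logisticCrossingTime()` provides the closed-form crossing oracle the
tests compare against. Group presets (`groupPresets()`) encode the
qualitative structure the assay shows in AD cohorts: control curves flat;
AD seeds in a minority of samples (19/43) with later t₅₀ and lower
amplitude; AD+LB seeds almost always, earlier and higher; APOE4 carriers
reach higher plateaus within AD+LB and LBD. Default magnitudes (baseline
≈ 10⁴ AU, positive plateaus ≈ 0.6–1.9 × 10⁵ AU, noise SD 800 AU) sit in
the range typical of ThT plate-reader exports, where strong seeded
fractions average around 2 × 10⁵ AU. These presets are the package's
fixed study conditions, chosen once for plausibility, not tuned.

## Microscopy quantification

### FRET inclusion detection

Biosensor cells seeded with α-SYN aggregates form intracellular inclusions
visible in the FRET channel. `detectInclusions()` reproduces the standard
recipe: binarize (Otsu by default — parameter-free and standard, with a
fixed-level override for full reproducibility), morphologically close with
a 10 × 10 px square structuring element ("width 10 pixels" is read as a
10 × 10 element), label 8-connected regions, and keep regions with
eccentricity < 0.8 and area between 4 and 1000 px, bounds inclusive.
Eccentricity comes from the ellipse with the same normalized second
central moments as the region, including the 1/12 per-pixel variance
correction (the regionprops convention), so a single pixel is a circle
(eccentricity 0) and a 2 × 50 bar scores ≈ 0.999. Region intensity is
always summed over the *raw* pre-threshold image. Masks are padded with
background before morphology so that objects near the canvas edge are not
smeared by border handling.

The percent of inclusion-positive cells needs a cell delineation the FRET
images do not provide; `percentInclusionPositiveCells()` uses an explicit
stand-in — a nucleus is positive when a kept inclusion centroid lies
within a configurable radius (default 15 px) of its centroid.

### Neurite length per nucleus

8-bit images are first passed through the tanh contrast filter
(`tanhContrast()`): min–max rescale to [0, 1], y = m(x − b) + 0.5 with
m = 2, b = 0.4 (the red/TUJ1-channel values), tanh, then min–max
renormalization to [0, 255]. The map is strictly monotone before
renormalization, so pixel ordering is preserved; a constant image has a
degenerate rescale and maps to zeros with a warning. Nuclei are detected
by erosion with a square element (default width 3 px), thresholding, and
keeping 8-connected regions of at least 50 px (erosion is applied to the
binarized image; with a flat square element this is mathematically
identical to grayscale erosion followed by thresholding). Detected nuclei
are dilated (default width 5 px) and subtracted from the binarized
neurite channel before skeletonization (Zhang–Suen thinning — absent from
the installed image stack, so implemented here; one-pixel-wide curves are
fixed points). Erosion/dilation widths and the minimum nucleus area are
not dictated by the recipe being reproduced; the defaults are
config-exposed choices. Touching nuclei merge into one region — no
watershed splitting is attempted.

**Skeleton length** defaults to *geodesic* counting: orthogonally adjacent
skeleton pixels contribute 1, diagonally adjacent pairs √2, and a diagonal
pair that merely shortcuts two orthogonal steps is not double-counted.
A plain pixel count (one unit per pixel) is available as
`lengthMode = "pixel"`, but it systematically undercounts diagonal runs by
a factor √2 — a 45° line of Euclidean length L contains only ≈ L/√2
pixels — which would break the package's own ground-truth requirement that
measured lengths track Euclidean truth within 10% for axis-aligned and 45°
neurites alike. Geodesic counting is therefore the default; on purely
axis-aligned skeletons the two modes differ by at most one unit per
segment.

### The scene generator

`renderScene()` rasterizes disk nuclei (blue channel), disk inclusions and
1-px hard-rasterized (Bresenham, no anti-aliasing) neurite polylines (red
channel) on an 8-bit canvas, adds Gaussian noise, and clips to [0, 255]
*after* noise — as 8-bit acquisition would. Truth records exact counts and
Euclidean polyline lengths before noise. `randomScene()` additionally
enforces a minimum separation (default 14 px, safely above the 10-px
closing element) so closing cannot merge distinct objects. These scenes
are deliberately simpler than real micrographs: no uneven illumination, no
out-of-focus blur, no touching cells, no intensity gradients along
neurites. Passing the ground-truth suite therefore shows the measurement
chain is correct, not that segmentation is robust to the confounds of
real tissue imaging.

## Cohort association statistics

Analyte levels (α-SYN, tau, Aβ40, Aβ42, APOE in TBS/TBSX/FA extraction
fractions) and RT-QuIC outcomes are analysed with:

* `applyTransform()` — identity, square-root or natural-log per variable
  to tame skewness (invertible for reporting; domain violations name the
  offending case). The per-variable assignment is study-specific and
  config-driven; α-SYN outcomes default to the square-root scale.
* `ordinalize()` — RT-QuIC outcomes are non-normal, so PAR is converted to
  3 levels at its 50th/75th percentiles and MaxFL to 4 levels at
  25th/50th/75th. Quantiles use linear interpolation between order
  statistics (R type 7, the common default — documented because level
  boundaries shift under other conventions); ties at a cutpoint go to the
  lower level; quantiles are computed on the analysis set itself, since
  the assay outcomes exist only there.
* `fitLinear()` / `fitPropOdds()` — OLS and proportional-odds
  (cumulative-logit) models, P(Y ≤ j|x) = logistic(αⱼ − βᵀx), adjusted for
  the usual covariate set (age at death, sex, CAA score, Braak stage, Thal
  phase, with or without APOE4 allele count). Both report Wald 95% CIs
  (matching the symmetric ±1.96·SE intervals of published association
  tables) rather than profile intervals; ordinal fits additionally report
  OR = exp(β). The ordinal fitter is `MASS::polr`; its estimates are
  verified in the test suite against an independent `optim()` maximizer of
  the hand-written likelihood (`cumulativeLogitNLL()`), and separation or
  non-convergence is surfaced as a failed fit with a diagnostic, never
  silently.
* `bonferroniThreshold()` — per-family α/m, annotated at 4 decimals
  (12 tests → 0.0042, 16 → 0.0031).
* `groupCompare()` — the functional-study rule: with any group of ≤ 8
  observations, rank tests have very low power, so a Student t test (two
  groups) or one-way ANOVA is used; larger groups get Mann–Whitney U or
  Kruskal–Wallis. All tests two-sided.

`simulateCohort()` draws covariates on plausible autopsy-cohort ranges
(age 55–100, Braak concentrated in IV–VI, Thal in 4–5) and an ordinal
outcome from the cumulative-logit model with known β and cutpoints. The
recovery benchmark (200 cohorts of n = 500, β = 0.8, cutpoints −1/0/1)
checks both point recovery (mean β̂ within 0.05) and Wald-CI coverage
(within [0.91, 0.98]); n = 500 with three well-populated interior levels
keeps each fit fast and the asymptotics honest.

## SEC fraction profiling

Sequential TBS brain lysates fractionated on tandem SEC columns
(0.8 ml/fraction; fractions #18–#56 collected) are profiled as
percent-of-total over the collected range — the denominator the published
elution plots use — which makes profiles invariant to loading amount.
`peakFractions()` reports interior local maxima (strict within a
configurable window; plateaus once, at their lowest fraction index;
endpoints never peaks). `mwAtFraction()` interpolates log₁₀(MW) linearly
against fraction index through marker points and refuses to extrapolate;
calibration must be strictly decreasing in MW (larger species elute
first). A small synthetic calibration table covering 2000–1.3 kDa ships in
`inst/extdata/` for examples. `compareProfiles()` tests each fraction
across groups on the percent scale (never raw amounts) via
`groupCompare()`, with Šidák correction across fractions by default.
Note that percent normalization couples fractions: a large shift at one
fraction depresses all others' percentages, so neighbouring fractions can
reach nominal significance — the injected-shift test asserts the shifted
fraction is the strongest signal, not the only one.

## Numerical conventions and degenerate inputs

* Thresholds use the sample (n−1) SD; fewer than 2 pooled readings is an
  error, zero variance is not.
* Crossing times snap *up* to the grid (first cycle at or above
  threshold).
* Constant images map to zeros under `tanhContrast()` (degenerate min–max)
  with a warning; empty masks yield empty region tables, not errors.
* All generators accept a `seed` and are bit-reproducible under it,
  without disturbing the caller's RNG stream.
* Area bounds [4, 1000] and the eccentricity cutoff are applied exactly as
  stated (inclusive bounds, strict < 0.8); every reported region satisfies
  them by construction and the suite property-tests this on random scenes.

## Problem sizes used in the test suite

The bundled suite runs entirely on synthetic data at desk scale: plates of
18–129 wells, 100-well crossing-oracle sweeps, 50 rendered 192² scenes,
200 ordinal cohorts of n = 500, and 10 000-case marginal checks — sizes
chosen so the whole suite completes in well under a minute per module
while leaving the statistical assertions comfortably powered.

## Known limitations

* The image pipeline quantifies single 2-D fields: no 3-D stacks, no
  spectral unmixing, no watershed splitting of touching nuclei, no
  cell-body segmentation (the inclusion-positive-cell denominator is the
  nucleus-proximity stand-in described above).
* The logistic curve family cannot represent biphasic or drifting-baseline
  ThT curves; the scoring functions themselves are model-free and handle
  any monotone-plateau curve.
* Proportional odds is assumed, not tested, in the ordinal models — as in
  the analyses this machinery reproduces.
* SEC profiling does not deconvolve overlapping peaks or fit peak areas;
  peak calls are strict local maxima on the sampled profile.
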