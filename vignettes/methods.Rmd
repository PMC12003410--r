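---
title: "Semi-automated muscle architecture measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated muscle architecture measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclearch)
```

## The measurement problem

In a longitudinal B-mode ultrasound view of a pennate muscle such as the
vastus lateralis, the muscle is bounded by two bright (hyperechoic)
connective-tissue sheets — the superficial and deep aponeuroses — and the
fascicles run obliquely between them. Three quantities summarize the
architecture:

* **Muscle thickness (MT)**: the vertical distance between the aponeuroses.
* **Pennation angle (PA)**: the angle at which fascicles insert into the
  deep aponeurosis. Measuring PA against the deep aponeurosis, rather than
  against the image horizontal, makes the measure insensitive to
  aponeurosis angulation, which changes with contraction intensity.
* **Fascicle length (FL)**: the straight-line path of a fascicle between
  the two aponeuroses. Because the fascicle usually leaves the field of
  view, FL is obtained by linear extrapolation and routinely exceeds the
  imaged width.

Manual measurement of these quantities is slow and, for novice raters,
unreliable. `musclearch` implements a semi-automated pipeline in which the
user supplies only three regions of interest (the parent muscle region and
the two aponeurosis bands) and the geometry is computed deterministically
from the pixels.

## The pipeline

1. **Aponeurosis model.** Pixels inside each aponeurosis ROI are
   binarized with Otsu's threshold computed on the ROI pixels, then closed
   (3×3 box) and hole-filled. Connected components below
   `aponeurosis.min_area_px` (default 100 px) are removed as regions
   discontinuous with the aponeurosis; if everything is below the cutoff
   the largest component is kept so a non-empty input can never become
   empty. The band's midline is, per occupied column, the midpoint
   `(min_row + max_row) / 2` — insensitive to interior holes — and is
   fitted with first- and second-order polynomials by ordinary least
   squares. The linear fit drives the PA/FL geometry; the quadratic fit
   absorbs curvature for the thickness measure.

2. **Muscle thickness.** MT is the vertical distance between the two
   quadratic fits, evaluated at 20%, 50%, and 80% of the parent ROI
   x-extent (the imaged aperture) and converted to cm with the
   pixels-per-mm calibration. Vertical (constant-x) distance matches the
   manual definition of thickness; a perpendicular mode is available via
   `thickness.mode = "perpendicular"` for sensitivity analysis. Crossed
   fits raise an error rather than returning a negative thickness.

3. **Fascicle candidates.** The parent ROI is binarized with a local-mean
   adaptive threshold: a pixel is foreground iff its intensity exceeds
   `(1.15 - 0.2 * sensitivity)` times the mean of its square
   neighborhood, whose side is the odd integer nearest one eighth of the
   smaller ROI dimension. At the default sensitivity 0.5 the factor is
   1.05, deliberately above the neutral value 1: thresholding a
   featureless region exactly at its local mean marks half of its pixels
   no matter how weak the noise is, and the resulting excursion set
   percolates into large connected clumps. Each 8-connected component is
   traced and reduced to the region properties of its moment-equivalent
   ellipse (area, centroid, orientation, eccentricity, major axis length,
   with the 1/12-px single-pixel variance correction so one-pixel-wide
   lines keep a finite minor axis). Candidates are kept when the area is
   between 75 and 6,000 px inclusive, the eccentricity is at least 0.90,
   and the centroid lies strictly between the linear aponeurosis fits.

4. **Extrapolation and architecture.** Each candidate defines the line
   through its centroid with slope `tan(orientation)` (y-up). The line is
   intersected in closed form with both linear fits; PA is the axial
   angle between the fascicle and the deep fit folded into [0, 90]°, and
   FL is the Euclidean distance between the two intersection points in
   cm. Intersections must fall within a finite extrapolation domain — the
   ROI extent extended by `fascicle.max_extrapolation_widths` ROI widths
   (default 4) on each side, about 20 cm of reach at a 5 cm aperture.
   This mirrors segment-based intersection testing: a fascicle may
   legitimately extrapolate several image-widths past the field of view,
   but a near-horizontal speckle streak whose "intersection" lies tens of
   image-widths away would otherwise contribute a non-physical
   1/sin(PA)-amplified length. Such candidates are rejected with reason
   `out_of_domain`; exactly parallel ones with reason `parallel`.

5. **Manual reference.** The manual method measures MT as the vertical
   aponeurosis separation and computes `FL = MT / sin(PA)`. On flat,
   parallel aponeuroses the semi-automated outputs satisfy the same
   identity, `FL * sin(PA) = MT`, which the test suite verifies to within
   1% per fascicle — the two methods agree by construction on ideal
   geometry and differ only through image noise and aponeurosis
   curvature.

Per-image summaries are arithmetic means over accepted fascicles; the
fascicle count, medians, and SDs are also reported. All geometry uses
0-based raster coordinates (x = column, y = row, depth increasing
downward); reported angles are y-up, positive rising toward the skin.

## Reliability statistics

Reliability work compares repeated measurements across trials, raters, and
methods on a long-format table keyed by subject, contraction intensity
(rest, 30%, 70%, 100% MVIC), rater, trial, and method.

* **ICC.** Both absolute-agreement intraclass correlations are derived
  from the two-way ANOVA mean squares (`MS_R` subjects, `MS_C`
  measurements, `MS_E` residual): the single-measure form
  `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` for
  intra-rater contrasts (the two-way mixed, single-rater, absolute
  agreement ICC shares this point estimate with the two-way random form),
  and the average-measure form ICC(2,k)
  `(MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)` for inter-rater contrasts.
  Confidence intervals use the standard F-based construction for
  absolute agreement; average-measure bounds step up the single-measure
  bounds with the Spearman–Brown relation. Estimates can be negative and
  are reported as computed; interpretation labels are applied to
  `max(estimate, 0)`. Rows with missing cells are dropped listwise with
  a warning because the ANOVA decomposition requires complete cells.

* **Interpretation bands.** Below 0.50 poor, 0.50–0.75 moderate,
  0.75–0.90 good, above 0.90 excellent. The published wording overlaps at
  the cutpoints, so the bands are closed deterministically as `< 0.50`,
  `[0.50, 0.75]`, `(0.75, 0.90]`, `> 0.90`.

* **Pearson.** Sample correlation with the Fisher-z interval,
  `SE = 1/sqrt(n - 3)`.

* **Bland–Altman.** Bias = mean difference, limits of agreement at
  `bias ± 1.96 × SD` (the multiplier is configurable but fixed at 1.96 by
  default), CI of the bias via `t · SD/sqrt(n)` and of each limit via
  `t · SD · sqrt(3/n)`.

`reliability_report()` assembles, per measure × intensity × method, the
intra-rater ICC (trial 1 vs 2 of the repeated rater), the inter-rater
ICC(2,k) across raters at trial 1, the across-trial Pearson correlation,
and per-measure pooled Bland–Altman statistics for manual vs
semi-automated values (subject–intensity cells averaged across raters at
trial 1). Missing design cells skip the affected contrast with a warning.

## The synthetic phantom

`generate_phantom()` renders a synthetic longitudinal view with analytic
ground truth: two bright aponeurosis bands along configurable linear or
quadratic center lines, oblique fascicle stripes at a known y-up angle
spanning the space between the band midlines, area-coverage (anti-aliased)
edges so stripe moments are stable across angles, and seeded
multiplicative speckle. The default conditions emulate the imaging setup
the pipeline targets: a 50 mm aperture at 10.2 px/mm (510 px wide), 5 cm
depth, ~2.8 cm muscle thickness, 15° fascicles, and a 10 px band
thickness.

Three generator choices deserve explanation:

* **Correlated speckle.** The multiplicative noise field is smoothed with
  a 3 px box kernel and rescaled to the target SD (uniform half-range 0.2
  by default, i.e. SD ≈ 11.5% of the local level). Real speckle has a
  finite grain set by the resolution cell; independent per-pixel noise is
  not a meaningful stress test for a local-mean thresholder.
* **Stripe spacing 60 px (~6 mm).** Fascicular septa in vastus lateralis
  images recur every millimetre or two; even this deliberately sparse
  spacing keeps the ROI textured the way real muscle is. Texture matters:
  the local mean between stripes stays elevated, which is precisely the
  mechanism that keeps adaptive thresholding clean in real images.
* **Intensities** background 0.15, stripes 0.55, bands 0.85 give the
  bright-band/bright-stripe/dark-ground ordering of B-mode muscle with
  contrast comfortably above the speckle.

The analytic truth contains the pennation angle relative to the deep
line, the per-stripe chord length between the two midlines along the
stripe direction (for parallel lines every stripe has the same chord),
and the vertical midline separation at the 20/50/80% positions. For flat
phantoms the truth satisfies `FL·sin(PA) = MT` exactly.

What the phantom does *not* emulate: attenuation and depth-dependent
gain, anisotropic point-spread functions, curved fascicles, intramuscular
vessels and fat, and out-of-plane fascicle curvature. Passing the
recovery suite therefore demonstrates the geometry and statistics are
implemented correctly, not that the pipeline is robust to every clinical
image; on real data the user-supplied ROIs and the config thresholds
remain the operator's responsibility.

`generate_measurement_table()` simulates the reliability design (15
subjects × 4 intensities × 3 raters × 2 trials × 2 methods by default)
from an additive two-way mixed model per measure with configurable
subject/rater/interaction/error SDs, intensity shifts, and a fixed
manual-minus-semi-automated method bias (defaults −4.0 cm FL, +2.99° PA,
−0.19 cm MT, matching the magnitude of reported between-method
differences). With all SDs zero every downstream ICC is exactly 1; the
theoretical single-measure absolute ICC across raters is
`σ_s² / (σ_s² + σ_r² + σ_i² + σ_e²)`.

## Numerical choices and degenerate inputs

* Intensities are rescaled by declared bit depth, never by observed
  min/max, so thresholds do not become doubly content-dependent.
  Calibration is always supplied (argument or sidecar), never inferred
  from pixels.
* Otsu's threshold uses 256 bins and returns the upper edge of the
  maximizing bin, so strict `>` cleanly excludes the background mode.
* Moment-degenerate regions (squares, discs) take orientation 0° and
  eccentricity 0; they can never pass the 0.90 eccentricity gate.
* Lines within 1e-9 of parallel slope are treated as non-intersecting.
* ICC tables with zero total variance are an error ("degenerate table");
  identical columns with subject variance give exactly 1, and in the
  no-measurement-variance limit the CI collapses to the estimate.
* Monte-Carlo validation of ICC recovery compares the ICC formed from
  replicate-averaged mean squares with the theoretical value: mean
  squares have exact variance-component expectations, whereas the
  per-replicate ratio estimator carries an O(1/n) small-sample bias that
  would dominate a naive mean-of-estimates comparison.
* Problem sizes in the validation suite — a 20-phantom recovery grid over
  PA ∈ {10, 15, 20, 25}° × deep slope ∈ {0, 5, 10}°, 1,000 random masks
  for the filter oracle, 500 tables for the ICC oracle, 1,000 replicates
  for ICC recovery, and 10,000 paired differences for Bland–Altman —
  were chosen to make Monte-Carlo error small relative to every tolerance
  while keeping the whole suite fast enough to run on every change.

## Known limitations

* Fascicles are modeled as straight lines; curved-fascicle tracking and
  time-series tracking across a contraction are out of scope, as is
  extended-field-of-view stitching.
* The shape filters (area, eccentricity, centroid position) are not
  texture classifiers: in a featureless, speckle-only region the adaptive
  threshold will still mark noise excursions, and occasionally one is
  elongated enough to pass. Dense fascicular texture — present in real
  muscle images and in the default phantom — suppresses this by keeping
  the local mean high; operators analyzing unusually echo-poor regions
  should raise the sensitivity threshold or tighten the filter bounds.
* DICOM input is not supported in this build; convert to PNG or
  single-frame TIFF.
* The reliability module reproduces the computations of the published
  workflow, not any cohort's numbers: those depend on raw images and
  rater behaviour.
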