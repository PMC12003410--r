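# musclearch

Semi-automated measurement of skeletal muscle architecture — muscle
thickness (MT), pennation angle (PA), and fascicle length (FL) — from
longitudinal B-mode ultrasound images of pennate muscle, for researchers
and clinicians who need reproducible architecture measures without the
rater variability of fully manual tracing. The package also provides the
manual-method reference formulas, the complete reliability workbench
(intraclass correlations, Pearson correlations, Bland–Altman statistics)
used to compare raters and methods, and a synthetic speckle-phantom
generator with analytic ground truth that validates every stage.

## The method

The user supplies a grayscale image, a pixels-per-mm calibration, and
three regions of interest: the parent muscle region and the superficial
and deep aponeurosis bands. The pipeline then:

1. binarizes each aponeurosis ROI (Otsu threshold on ROI pixels, 3×3
   closing, hole filling), removes small discontinuous regions, extracts
   the band midline (per-column `(min + max)/2`), and fits first- and
   second-order polynomials;
2. measures MT as the vertical distance between the quadratic fits at
   20%, 50%, and 80% of the aperture width:
   `MT(x_p) = (y_deep(x_p) − y_sup(x_p)) / (px/mm · 10)` cm;
3. adaptively binarizes the parent ROI (local-mean threshold), traces all
   8-connected hyperechoic regions, and keeps line-like fascicle
   candidates with area ∈ [75, 6000] px, eccentricity ≥ 0.90, and
   centroid between the first-order aponeurosis fits;
4. extrapolates each fascicle through its centroid at its
   moment-ellipse orientation θ, intersects it with both linear fits,
   and reports

   - pennation angle `PA = |θ_fascicle − θ_deep|` folded into [0, 90]°
     (measured against the deep aponeurosis, not the horizontal), and
   - fascicle length
     `FL = √((x_deep − x_sup)² + (y_deep − y_sup)²) / (px/mm · 10)` cm.

The manual reference method is `FL = MT / sin(PA)`; on flat parallel
aponeuroses the semi-automated outputs satisfy the same identity.

Reliability statistics follow the standard two-way ANOVA forms: the
single-measure absolute-agreement ICC
`(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))` for
intra-rater contrasts, ICC(2,k) for inter-rater contrasts, F-based 95%
confidence intervals, the poor/moderate/good/excellent bands at
0.50/0.75/0.90, Fisher-z Pearson intervals, and Bland–Altman limits of
agreement at `bias ± 1.96·SD` with their confidence intervals.

## Worked example

A phantom stands in for a real image so the example is fully
reproducible; the same calls work on data from disk via `read_bmode()`
and `load_roi()`.

```r
library(musclearch)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 510x510 px, 10.2 px/mm
res <- analyze_image(ph$image, ph$rois)
res
#> <muscle_architecture> phantom_seed1
#>   fascicles: 24 accepted (of 24 candidates, 30 regions)
#>   pennation angle: 14.94 deg (mean), fascicle length: 10.82 cm (mean)
#>   muscle thickness (20/50/80%): 2.787/2.786/2.787 cm, mean 2.787 cm
```

The phantom's analytic truth is PA 15°, FL 10.818 cm, MT 2.800 cm: the
pipeline recovers the pennation angle to 0.06°, fascicle length to 0.1%,
and thickness to 0.5%. `tidy(res)` returns the per-fascicle table
(intersection points, PA, FL), `glance(res)` the one-row image summary,
and `write_results()` exports the long-format CSV/JSON. Batch processing
over a manifest CSV is `run_batch()`, and
`inst/scripts/muscle-arch.R` wraps analyze/batch/reliability/phantom as
shell commands.

Reliability of a measurement campaign (here simulated with known
variance components):

```r
tab <- generate_measurement_table(seed = 1)   # 15 subjects x 4 intensities
rep <- reliability_report(tab)                #   x 3 raters x 2 trials x 2 methods
dplyr::select(rep$icc, measure, intensity, method, contrast, estimate, label)
#> 1 FL_cm   rest      manual intra_rater    0.960  excellent
#> 2 FL_cm   rest      manual inter_rater    0.985  excellent
#> ...
rep$bland_altman[, c("measure", "bias", "loa_low", "loa_high")]
#> 1 FL_cm   -3.83   -4.85    -2.81
#> 2 MT_cm   -0.163  -0.212   -0.114
#> 3 PA_deg   2.81    2.02     3.60
```

The Bland–Altman rows recover the simulated manual-minus-semi-automated
method biases (−4.0 cm FL, −0.19 cm MT, +2.99° PA). `autoplot()` methods
draw the image overlay and the Bland–Altman plot;
`plot_reliability(rep)` shows every ICC with its interval against the
interpretation bands.

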