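Package: musclearch
Title: Semi-Automated Muscle Architecture Measurement from B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated extraction of muscle thickness, pennation angle,
    and fascicle length from longitudinal B-mode ultrasound images of pennate
    muscle. User-supplied aponeurosis regions are cleaned, reduced to
    midlines, and fitted with first- and second-order polynomials; the
    muscle region is adaptively binarized and hyperechoic regions are
    filtered by area, eccentricity, and centroid position to identify
    fascicles, which are linearly extrapolated to the aponeurosis fits to
    yield pennation angle (relative to the deep aponeurosis) and fascicle
    length. Includes the manual-method reference formulas, a reliability
    workbench (two-way absolute-agreement intraclass correlation
    coefficients with confidence intervals and interpretation bands, Pearson
    correlation with Fisher intervals, Bland-Altman bias and limits of
    agreement), and a synthetic speckle-phantom generator with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
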