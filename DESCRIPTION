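Package: gaitstab
Title: Gait Stability and Fatigue Recovery from Waist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies walking stability of workers from waist-worn tri-axial
    accelerometer recordings using dynamic time warping (DTW) against each
    person's own non-fatigued reference gait. Provides signal-vector-magnitude
    preprocessing with Hampel outlier filtering, peak-based gait-cycle
    segmentation, a from-scratch DTW core with warp-path backtracking,
    hazard-zone stability aggregation across fatigue levels and walking-surface
    conditions (obstacle, water, oil), and logarithmic recovery-time estimation
    from post-hazard per-cycle DTW decay. Includes a seeded synthetic-cohort
    generator with calibrated hazard perturbations and known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
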