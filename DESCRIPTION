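Package: jlmorph
Title: Distal Femoral Joint-Line Morphometry from Epicondylar Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometry of the distal femur for joint-line reconstruction in
    revision knee arthroplasty. Builds the femoral anatomical and mechanical
    axes and the axial and coronal measurement planes from a bone surface
    mesh, detects the epicondylar prominences and condylar extremes, and
    measures the distances from the medial and lateral epicondyles to the
    posterior and distal joint lines together with the transepicondylar width
    and the distance-to-width ratios. Includes a parametric synthetic femur
    generator with analytic ground truth, cohort statistics (summaries with
    confidence intervals, Pearson correlation, two-way random-effects
    intraclass correlation, and exact power for the correlation test), and
    ratio-based prediction of joint-line offsets from femoral width.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
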