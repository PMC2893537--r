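Package: plrkit
Title: Dynamic Pupillometry: Pupil Detection and Light-Reflex Parameterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for dynamic pupillometry from infrared eye-image
    sequences. Implements the offline image pipeline used to measure pupil
    and iris radius per frame (specular-glint elimination, high-boost edge
    enhancement with gamma correction, Canny edge detection, sub-pixel
    circle-template correlation fitting and circular Hough iris
    localization), builds radius-versus-time pupillograms, extracts the
    standard single-flash and 25-flash pupil-light-reflex parameters
    (latencies, pupil/iris ratios, reflex amplitude, constriction
    velocity) with blink detection and exclusion, and provides the
    group-comparison statistics (one-way ANOVA with Bonferroni post-hoc,
    Kruskal-Wallis) used in autonomic-neuropathy screening studies. A
    synthetic eye-image generator with analytic ground truth makes every
    stage testable without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
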