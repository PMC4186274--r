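Package: parallaxdepth
Title: Perceived Depth from Motion Parallax via the Motion/Pursuit Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling perceived depth magnitude from motion
    parallax with the motion/pursuit ratio. Implements the exact and
    approximate geometric depth laws linking retinal image motion and
    pursuit eye-movement rates to relative depth, the distance-square law
    for binocular disparity, a power-law "empirical motion/pursuit ratio"
    transducer model, cumulative-normal psychometric function fitting
    (PSE and sigma) for two-interval forced-choice depth matching,
    log-space least-squares plane fitting that recovers transducer
    exponents, a synthetic 2IFC observer that emulates head-stationary,
    head-translating and depth-constancy control sessions, and an
    end-to-end simulate/fit/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
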