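Package: odorspace
Title: Perceptual Encoding Models and Capacity Estimates for Odor
    Discrimination Psychophysics
Version: 0.1.0
Authors@R:
    person("Odorspace", "Developers", email = "odorspace@example.org",
           role = c("aut", "cre"))
Description: Simulates odd-man-out (triangle test) odor-mixture
    discrimination experiments under three perceptual encoding models --
    a deterministic three-category sum-threshold responder, trichromatic
    linear mixing with additive Gaussian coordinate noise, and a
    one-dimensional circular (ring) code with angular noise -- and
    evaluates the sphere-packing (Hamming bound) extrapolation from
    critical discrimination distance to the number of discriminable
    stimuli, using exact big-integer combinatorics. Includes
    overlap-controlled synthetic mixture designs, psychometric curve
    estimation with critical-distance extraction, noise calibration to a
    just-noticeable difference, sphere-coloring lower bounds on the number
    of percepts, and reproducible figure/report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
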