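Package: ccmotion
Title: Co-Confident Motion Analysis for Visuomotor Tracking and Mirror Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when a follower's movement becomes co-confident
    (CC) -- synchronized, smooth and jitter-free -- while tracking rhythmic
    one-dimensional motion, as in the experimental mirror game. Builds
    piecewise half-sine stimulus programs with cubic join blending, detects
    acceleration zero crossings (AZC), jitter points and CC segments in
    tracking responses, quantifies cross-participant similarity of CC
    placement with Hamming distances against a trial-shuffled null, and
    estimates how CC probability depends on stimulus frequency and peak
    velocity (per-participant regression slopes, frequency binning of free
    two-player motion, mixed-design ANOVA across experiments). Includes a
    generative intermittent-control follower built from minimum-jerk
    submovements with a stochastic ceiling on smooth-movement duration, so
    the whole pipeline can be exercised on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
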