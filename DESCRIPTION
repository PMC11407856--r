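Package: jumpnat
Title: Projectile-Motion Models of Perceived Naturalness of Human Jumping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers judge the naturalness of human
    jumping motion from its vertical trajectory. Represents flight-phase jump
    trajectories, modulates them in height and duration, recovers projectile
    parameters (initial velocity and effective gravity) by least squares, and
    scores each modulated jump with three families of naturalness statistics
    derived from vertical projectile motion: deviation of the modulation
    ratios from the theoretical curve T = sqrt(H), root-mean-square disparity
    between observed and predicted height, velocity and acceleration
    trajectories, and prediction errors in time-to-apex and maximum height.
    Includes rank-correlation analysis of model scores against visual-analogue
    naturalness ratings, participant-bootstrap model comparison with
    Bonferroni correction, a gravity-sweep fit, and a synthetic-data generator
    (jump trajectories, point-light marker tables, and observer ratings) so
    the full pipeline can be exercised and validated without motion-capture
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
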