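Package: delaystate
Title: Structure and Variability of Preparatory Neural Population States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of delay-period (motor preparatory) population
    activity from multielectrode array recordings in an instructed-delay
    center-out reaching task. Builds a low-dimensional "initial condition"
    subspace by PCA on condition-averaged firing rates followed by
    sequential orthogonalized regression onto reach endpoint (x, y) and
    maximum reach speed; decomposes trial-to-trial variability of the
    neural state into on-axis (distance) and off-axis (direction)
    components; and quantifies endpoint decodability with cross-validated
    support-vector classification and angle, arc-length and distance
    error metrics. Includes a synthetic trial generator with the same
    statistical structure (linear population encoding, speed-distance
    correlation, radially anisotropic endpoint variability) so every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
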