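Package: reachfn
Title: Functional Networks and Trajectory Encoding Models for Sensorimotor
    Spiking During Naturalistic Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links single-unit sensorimotor spiking to temporally extended
    hand kinematics and to a directed functional network estimated with
    confluent mutual information (conMI) between binarized spike trains.
    Provides marker-trajectory cleaning, Savitzky-Golay smoothing and reach
    segmentation; extraction of paired velocity-trajectory/spike samples;
    L2-penalized Poisson encoding models scored by ROC AUC over resampled
    train/test splits; integration of fitted velocity coefficients into
    preferred-path pathlets; network-feature terms built from conMI edge
    weights; strong-edge permutation analyses of the functional network; and
    classification of context-specific versus context-invariant functional
    groups across reaching and spontaneous behavior. A coupled log-linear
    point-process simulator with known ground truth makes every stage of the
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
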