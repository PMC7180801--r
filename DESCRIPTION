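Package: relimb
Title: Deep-Learning-Refined Upper-Limb Kinematics from a Single Depth Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional shoulder and elbow joint angles from a
    single depth-sensor skeleton stream and from a marker-based optical motion
    capture gold standard (UWA upper-limb model with CAST cluster
    reconstruction), learns a sequence-to-sequence LSTM correction that maps
    the depth-sensor angle waveforms toward the gold standard, and quantifies
    agreement (Kadaba coefficient of multiple correlation, RMSE, range of
    motion, angle at target, Bland-Altman limits of agreement) under
    leave-one-subject-out cross-validation. Includes a synthetic motion and
    sensor-error simulator that generates paired skeleton/marker corpora for
    four upper-limb functional tasks, so the whole pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
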