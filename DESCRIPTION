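Package: subglot
Title: Subglottal Pressure Estimation from Vocal-Fold Trajectories via a
    Simulation-Trained Recurrent Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the subglottal pressure driving vocal-fold
    oscillation from short medio-lateral edge trajectories, as extracted from
    high-speed video of phonating larynges. A lumped-element two-mass model of
    the vocal folds generates labeled synthetic trajectory pairs across a wide
    space of mass, stiffness, collision and pressure configurations; the
    trajectories are augmented with measurement noise and slow amplitude
    modulation to resemble experimental recordings; the scalar pressure target
    is discretized into Gaussian-balanced classes; and a recurrent (LSTM)
    classifier trained once on the synthetic data replaces per-recording
    optimization of the physical model. Includes the fixed-step simulator,
    sustained-oscillation detection, dataset synthesis with provenance,
    balanced quantile binning, the recurrent classifier with training and
    prediction utilities, error metrics, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
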