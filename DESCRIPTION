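Package: braid
Title: Behaviorally Relevant Analysis of Intrinsic Dynamics with Measured Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Input-driven nonlinear latent dynamical modeling of simultaneously
    recorded neural activity and behavior. Fits recurrent state-space models
    that jointly learn a predictor-form recursion (for causal state inference
    from neural observations and measured inputs) and a generative-form
    recursion (for multi-step forecasting driven by inputs alone), so that
    intrinsic population dynamics are disentangled from the dynamics of
    measured external inputs. A multi-stage optimization scheme prioritizes
    the latent dynamics shared with behavior, then captures neural-specific
    dynamics, and can dissociate input-driven behavior-specific dynamics that
    are not encoded in the recorded neural activity. Includes simulation
    utilities with ground-truth oracles, automatic per-map nonlinearity
    selection, cross-validated evaluation (correlation coefficient, R-squared,
    eigenvalue recovery of the intrinsic state-transition map), and a
    command-line interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
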