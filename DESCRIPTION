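Package: redyn
Title: Reliable Dynamics Representation Modelling of Force-Field Generalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how learned velocity-dependent force-field dynamics
    generalize across arm workspaces under Cartesian, joint-torque, and
    object-centred coordinate frames. Provides planar two-link arm kinematics,
    scaled and unscaled curl force fields, per-frame generalized force
    predictions, frame-mixture weights computed by Monte-Carlo propagation of
    planning noise (inverse-variance weighting) as well as energy, smoothness
    and data-fitted alternatives, a synthetic force-channel experiment
    generator, and model-comparison statistics (force-compensation slopes,
    circular phase shifts, RMSE and BIC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
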