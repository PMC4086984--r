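Package: kneepca
Title: Post-Hoc Correction of Kinematic Cross-Talk in Knee Joint Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes kinematic cross-talk from three-dimensional knee joint
    angles (flexion/extension, ab/adduction, axial rotation) caused by
    misalignment of the marker-derived joint coordinate system. One principal
    component analysis is fitted per subject and side on gait cycles stacked
    over time; the sorted, sign-fixed eigenvector matrix defines an orthonormal
    transfer matrix that maps observed Cardan angle triples onto corrected
    anatomical angles and can be transferred to a static posture trial.
    Includes Cardan/Euler rotation utilities, gait-cycle preprocessing
    (spline gap filling, smoothing, event detection, 101-point time
    normalization), evaluation statistics (cross-talk r-squared, kinematic
    profile variance, posture-versus-radiograph comparison), and a seeded
    synthetic gait generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
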