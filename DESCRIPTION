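Package: glenosim
Title: Muscle-Actuated Glenohumeral Shoulder Simulator with Cascade/Parallel
    PID Force Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software-in-the-loop shoulder simulator: a rigid-body virtual
    specimen of the glenohumeral joint driven by six cable muscles (three
    deltoid heads and the rotator cuff), controlled by three independent
    per-degree-of-freedom loops with activation and distribution PID
    controllers switched between cascade loading (active abduction) and
    parallel loading (active flexion/extension and axial rotation).
    Includes ISB-style Cardan XZY kinematics, pivot-based centre-of-rotation
    estimation, a seeded synthetic-specimen generator, the six standard
    motion protocols, and an evaluation pipeline computing accuracy (mean
    deviation, RMSE), repeatability (SD across repeats) and reliability
    (ICC(A,1) with 95% confidence intervals) at 1-degree increments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
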