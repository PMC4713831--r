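Package: fishtrack3d
Title: Automated 3D Tracking and Inverse Dynamics of Swimming Fish from
    Multi-Camera Silhouette Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a parameterised, curvature-deformed 3D body model of a
    fish to synchronised multi-camera high-speed video by silhouette
    matching with Nelder-Mead optimisation, recovering per-frame position,
    head orientation (Tait-Bryan angles) and midline curvature. Tracked
    kinematics are smoothed with a penalised least-squares (Whittaker)
    smoother and post-processed by inverse dynamics into centre-of-mass
    motion, resultant forces, angular momentum and resultant torques of
    the deforming body, using exact polyhedral volume integrals. Includes
    calibrated virtual cameras (orthographic and perspective), gradient
    based silhouette segmentation, and a synthetic-data module that
    regenerates the verification experiments (a simulated swimming larva
    with known motion, and a rigid cylinder driven by prescribed forces
    and torques) entirely in silico.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    pracma,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
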