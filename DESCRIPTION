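Package: fishTrack3D
Title: Two-View Motion-Based Tracking of a Single Fish with 3D Trajectory
    Metrics and Nonparametric Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive single-fish tracking from two orthogonal camera
    views of a rectangular tank. Per-frame detection combines empty-tank
    reference subtraction, dense polynomial-expansion optical flow, motion
    masking, Canny edge detection with morphological dilation, and convex-hull
    blob measurement. Matched front/top detections are fused into millimetre
    3D coordinates, from which per-second speeds, windowed speed means,
    cumulative swim distance and occupancy grids are derived. A statistical
    battery (descriptives, one-sample Kolmogorov-Smirnov screen,
    Kruskal-Wallis omnibus, Dunn post hoc with Bonferroni correction)
    compares treatment groups. A synthetic scene generator simulates bounded
    correlated-random-walk trajectories, renders both views, and provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
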