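Package: hyoidtrack
Title: Semi-Automatic Hyoid Bone Motion Tracking, Smoothing and
    Segmentation for Videofluoroscopic Swallowing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinematic analysis of the hyoid bone in lateral-projection
    videofluoroscopic swallowing studies (VFSS). Tracks seeded anatomical points
    frame-by-frame with Sobel edge-template matching under a bounded
    rotation-and-shift search, clips regions of interest occluded by the
    mandible so tracking survives masking, monitors tracking failures with a
    third-order motion predictor, denoises trajectories with cubic smoothing
    splines, calibrates them into a patient-centric C2-C4 coordinate system
    measured in cervical units, and automatically segments one swallow loop
    into elevation, anterior-movement, descending and returning phases using
    splitting scores on the velocity profile. Includes a ground-truthed
    synthetic phantom generator, agreement statistics (range of motion,
    relative errors, Pearson and intraclass correlation) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
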