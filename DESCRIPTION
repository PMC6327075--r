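Package: vestrack
Title: Single-Vesicle Spot Detection, Trajectory Tracing and Kinematics
Version: 0.1.0
Authors@R: person("Vestrack", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tracks undyed membrane vesicles in grayscale confocal image
    sequences. Detects point-like bright spots per frame with a
    Laplacian-of-Gaussian filter, threshold and connected-component
    labeling; links detections across consecutive frames through the
    pairwise distance matrix with a multi-cutoff nearest-neighbor search
    that classifies regular, merging, branching, ending and beginning
    segments; assembles trajectories in a compound segment store with
    merge resolution; and derives per-trajectory kinematics (velocity,
    speed, traveling distance, moving range) and summary statistics.
    Includes a synthetic-movie generator with scripted merge and branch
    events for ground-truth validation, a minimal uncompressed TIFF
    reader/writer, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
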