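Package: flockgaze
Title: Visual-Field Reconstruction and Escape Contagion in Foraging Bird Flocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the egocentric visual field of ground-foraging
    birds from motion-capture marker trajectories, and for analysing predator
    detection and collective escape. Provides rigid head-pose estimation from
    marker clusters, an eye/beak head-frame calibration with a 30-degree beak
    horizon offset, foveal (lateral, 75-degree) projection of scene objects,
    head-saccade and fixation segmentation, a rule-based posture ethogram
    (feeding, grooming, courting, running away, flying, head-up/down),
    foveation-event extraction with minimum-duration and onset-exclusion rules,
    detection and escape latency metrics, visual-field heatmaps, and a
    matched-pair permutation test for social contagion of escape latencies with
    a distance-overlap control. A synthetic flock generator emulates a full
    motion-capture experiment (room, monitors, 60 Hz kinematics, scripted
    saccades, pecking and escape) with complete ground truth, so every pipeline
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
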