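Package: armkin
Title: Upper-Limb Kinematic Metrics from 3D Motion-Capture Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes clinically interpretable kinematic metrics from segmented
    3D upper-limb marker trajectories: movement time, mean and peak velocity,
    five smoothness measures (velocity ratio, velocity-peak count, acceleration
    zero-crossings, log dimensionless jerk, spectral arc length), hand path
    ratio, target error, time to peak velocity, and elbow/shoulder range of
    motion with a goniometer-style virtual trunk reference. Recordings are
    read from a canonical CSV marker schema with per-row iteration labels; a
    minimum-jerk synthetic motion generator provides recordings with
    analytically known kinematics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
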