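Package: oetplan
Title: Real-Time Path Planning for Multi-Particle Transport with
    Optoelectronic Tweezers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop planning and simulation toolkit for synchronously
    transporting multiple microparticles (polystyrene beads and cells) with
    optoelectronic tweezers. Provides detour-aware goal assignment via a
    Kuhn-Munkres solver, QMDP belief-space planning on a discretized
    workspace, two-level priority collision avoidance, a stochastic
    simulator of optically-induced dielectrophoresis trapping with Brownian
    motion and escape/retrap dynamics, and a synthetic visual-feedback
    chain (Hough circle detection, size classification, Kalman tracking),
    so the whole control loop runs and is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
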