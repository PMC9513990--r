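Package: ulbench
Title: Benchmarking Upper-Limb Motor Capacity from Kinematics and Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified benchmarking toolkit for upper-limb capacity assessment in
    neurological disorders. Encodes a motor primitive/skill/ability taxonomy with a
    registry of kinematic and electromyographic performance indicators, an 8-DOF
    upper-limb kinematic model (ISB convention) with robotics/ISB shoulder-angle
    conversion, taxonomy-driven trial segmentation with trunk-compensation validity
    rules, the full indicator suite (smoothness, accuracy, efficiency, planning,
    speed, EMG time/frequency features, co-contraction, intermuscular coherence,
    muscle synergies via non-negative matrix factorization), a standardized
    assessment protocol with a machine-readable worksheet and target layout, and a
    synthetic-trial simulator (minimum-jerk reaches, amplitude-modulated band-limited
    EMG) with ground-truth labels so the entire pipeline is testable without
    recorded patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
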