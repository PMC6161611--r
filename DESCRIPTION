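Package: rotorbench
Title: Virtual Benchmarking of Electrogram-Guided Rotor Mapping and Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico benchmark for electrogram-guided ablation of
    reentrant drivers (rotors) of atrial fibrillation. Simulates spiral-wave
    reentry with a monodomain reaction-diffusion solver on triangulated
    atrial-like surfaces, samples the extracellular potential field with
    virtual multi-electrode grid and basket catheters, reconstructs
    rotor-tip trajectories from the unipolar electrograms by phase mapping
    and phase-singularity tracking, summarises them as trajectory density
    maps, and applies sequential virtual radiofrequency lesions at the
    density peaks. Includes seeded synthetic-geometry and reentry fixtures
    so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
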