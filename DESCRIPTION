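Package: raffmap
Title: Rotating-Frame Relaxometry with RAFFn Pulse Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative rotating-frame magnetic resonance
    relaxometry. Constructs sampled radiofrequency waveforms for RAFFn
    (Relaxation Along a Fictitious Field, ranks 1-5) preparations including
    RAFF2 packets with a variable stretching factor, continuous-wave
    spin-lock, adiabatic hyperbolic-secant (HS1/HS4) and hard pulses;
    simulates relaxation during these irradiations with a two-pool
    Bloch-McConnell model with dipolar rates derived from a rotational
    correlation time; fits relaxation-rate and steady-state maps from
    paired +Z/-Z acquisitions with steady-state formation; and computes
    regional relative relaxation time difference (RRTD) contrast on a
    built-in short-axis cardiac phantom.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    deSolve,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'fitting.R'
    'contrast.R'
    'io.R'
    'phantom.R'
    'pulse-library.R'
    'spin-dynamics.R'
    'pipeline.R'
    'raffmap-package.R'
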