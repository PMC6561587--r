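Package: emir
Title: Cell-Based Simulation of Cardiac Conduction with the EMI Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates action-potential conduction along strands of explicitly
    meshed cardiomyocytes with the EMI (Extracellular-Membrane-Intracellular)
    model. Each cell, its membrane, the intercalated discs and the surrounding
    extracellular space are separate parts of a 3D finite-difference domain,
    advanced by operator splitting between the nonlinear membrane kinetics and
    an implicit solve of the coupled potential equations. Supports non-uniform
    sodium-channel placement at the cell ends with conserved whole-cell
    conductance, tunable per-disc gap-junction resistance, nanometre-scale
    junctional clefts for ephaptic-coupling experiments, a port of the Grandi
    epicardial human ventricular action-potential model, and the measurement
    pipeline (activation maps, conduction velocity, gap-junction delays,
    upstroke velocity, integrated sodium current, cleft-potential fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
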