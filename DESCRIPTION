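Package: rfevolve
Title: Genetic-Algorithm Evolution of Radial-Frequency Shape Distractors for Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolving radial-frequency (RF) pattern distractors that make
    visual search for a target shape harder or easier. Implements the RF genome
    (10 amplitudes, 10 phases, 10 on/off gates), contour synthesis and rasterization,
    three target-distractor shape-similarity parameterizations (medial-axis skeleton
    distance after best rigid alignment, the isoperimetric ratio perimeter^2/area as a
    total-curvature index, and the L2 distance between radial Fourier amplitude
    spectra), the evolutionary loop (elitist selection, uniform crossover, per-element
    mutation, per-frequency constraint masks), a synthetic observer that converts
    target-distractor similarity into simulated search reaction times, and a search
    experiment harness (blocked schedules, circular display composition, RT filtering
    and RT-by-set-size slope analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
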