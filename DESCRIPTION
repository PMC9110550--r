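Package: trackmech
Title: Cell-Matrix Mechanics and Morphometry in Collagen Microtracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies reciprocal cell-tissue mechanics of tumor cells
    migrating through laser-ablated collagen microtracks from multi-channel
    time-lapse stacks: drift stabilization, the reflection/fluorescence
    filtering recipe, kymographs, automated track-width dynamics, collagen
    speckle tracking by normalized cross-correlation, strain and linear-elastic
    traction-force estimation (F = E x strain x contact area), cell migration
    kinematics (speed including stop phases, path/beeline persistence, cell
    length, relative nuclear position), nuclear morphometry (minor diameter,
    irregularity index, counts, proteolysis index), and the matching
    nonparametric statistics (Kruskal-Wallis with Dunn post hoc, Mann-Whitney).
    Includes a seeded synthetic-scene generator that renders a migrating cell
    deforming a speckled collagen microtrack with known ground truth, so every
    stage of the pipeline is testable without raw microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
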