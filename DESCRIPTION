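Package: retinocycle
Title: Cell-Cycle Phase Calling and Vascular Zonation for FUCCI Retina Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying endothelial cell-cycle
    state in postnatal retina whole-mount images carrying a two-colour
    PIP-FUCCI reporter. Segments endothelial nuclei from an ERG nuclear
    stain, measures per-nucleus mean fluorescence intensity of the mVenus
    and mCherry reporter channels, assigns each nucleus a cell-cycle phase
    (G1/G0, S, G2) from data-driven positivity thresholds, assigns nuclei
    to manually annotated vascular zones (polygons plus tip/stalk nucleus
    lists), and computes per-retina per-zone phase proportions, capped
    G2/S and G2/G1 count ratios, marker concordance tables and group
    comparisons. Also segments single-cell time-lapse reporter traces into
    phases, measures phase durations, intermitotic intervals and per-phase
    migration metrics, and ships a synthetic-data generator (images, truth
    tables, zone annotations, traces) so every stage is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
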