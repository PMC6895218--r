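Package: opdensity
Title: Stereological Oocyte Packing Density and Fecundity Accounting
Version: 0.1.0
Authors@R:
    person("Galician Shelf", "Fisheries Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates stage-specific oocyte packing densities (oocytes per
    gram of ovary) from stereological grid counts and oocyte axis
    measurements, following the auto-diametric / packing-density approach
    used in fish fecundity research. Covers the full pipeline for a
    multiple-spawning, asynchronous species such as European hake: Delesse
    point-count volume fractions with field-count stabilization diagnostics,
    shape factors and volume-based diameters with shrinkage correction,
    the packing-density formula and whole-ovary oocyte numbers, three
    size-standardization routes (length classes, TL-cubed scaling backed by
    an allometric eviscerated-weight fit, and predicted gonad weight),
    spawning phenology (spawning fraction, season assignment), and the
    batch-fecundity accounting that turns cumulative stage oocyte numbers
    into potential fecundity, accumulated batches and spawning-season
    durations. A seeded synthetic-ovary module generates oocyte populations,
    sectioned histological fields with grid hits, whole-mount style axis
    measurements and fish cohorts, so every stage of the pipeline is
    verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
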