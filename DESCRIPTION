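Package: alpzone
Title: Altitudinal Zonation Analysis of Soil Green-Algae Metabarcoding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-sequencing analysis pipeline for soil eDNA metabarcoding
    surveys of green algae along elevational gradients. Provides MOTU-table
    quality control (amplicon length and rarity filters, target-clade
    restriction, negative-control contaminant removal, failed-PCR rejection,
    replicate-outlier detection), Hill-number diversity and its relation to
    discretized environmental gradients, Hellinger-based community turnover
    (principal coordinates, partial redundancy analysis with permutation-based
    forward-backward selection and variance partitioning), robust
    marker-versus-marker regression, and Outlying Mean Index niche inference
    with a dual permutation criterion for niche specialization. A synthetic
    study generator with known ground truth (niche optima, spiked
    contaminants, forced PCR failures) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
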