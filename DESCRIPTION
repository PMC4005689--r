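Package: hrfseq
Title: Saturation-Corrected Analysis of Hydroxyl Radical Footprinting by
    Massive Parallel Sequencing
Version: 0.1.0
Authors@R:
    person("HRF-Seq", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for sequencing-based hydroxyl radical footprinting (HRF) of
    RNA. Converts paired-end alignments of probed and control libraries into
    per-fragment records keyed by reverse-transcription termination and priming
    sites, corrects PCR duplication with a 7-nt random barcode model that
    allows unequal barcode frequencies (estimated unique counts, EUC), and
    derives per-position accessibility as the termination-coverage ratio of the
    treated library minus that of the control (delta-TCR), smoothed with an
    offset moving average. Includes structure-derived validation metrics
    (ribose bead through-space contact counts and dot-lattice solvent
    accessible surface area), a fully specified synthetic-experiment simulator
    with known cleavage probabilities, and a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
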