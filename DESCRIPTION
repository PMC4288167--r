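Package: tfocc
Title: Statistical-Thermodynamic Modelling of Transcription Factor Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical statistical-thermodynamics model of genome-wide
    transcription factor occupancy. Computes per-site binding probabilities
    from position weight matrix scores, DNA accessibility, the number of
    DNA-bound molecules (N) and a specificity scaling factor (lambda);
    converts occupancies into ChIP-seq-like coverage profiles via a
    fragment-length kernel; and infers N and lambda from observed binding
    profiles by grid search over Pearson correlation and mean-squared-error
    surfaces with a band-intersection selection rule. Includes a fully
    synthetic benchmark generator (random genomes with planted motif
    instances, block-structured accessibility, forward-simulated noisy
    profiles) and readers/writers for FASTA, BED, bedGraph, wiggle and
    JASPAR-style motif count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
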