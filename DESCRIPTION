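Package: oscindel
Title: Out-of-Frame Stop Codons and Indel-Driven Protein Loop Variation
Version: 0.1.0
Authors@R: person("Otc", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how hidden (out-of-frame) stop codons
    constrain insertion/deletion-driven evolution of protein loops in
    bacterial coding sequences. Scans and classifies out-of-frame stop
    codons (OSCs) in coding DNA; applies indel events to engineered
    frameshift constructs, translates them, and classifies
    gain-of-function outcomes; transplants indel events between synonymous
    +OSC/-OSC construct pairs (sequence reconstruction analysis);
    summarizes mutant spectra; profiles protein multiple alignments
    (column conservation, information content in bits, gap-aware
    coordinate mapping, anchor-delimited loop lengths by taxon); computes
    codon-space likelihoods that an amino-acid pair forms an OSC at its
    codon junction; and estimates mutation rates from Luria-Delbruck
    fluctuation tests by the Lea-Coulson method of the median, alongside
    stationary-phase mutagenesis frequency curves. A seeded
    synthetic-data module generates every input the pipeline consumes, so
    all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
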