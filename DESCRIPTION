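Package: genesynth
Title: Design of Tm-Matched Overlapping DNA Fragments for PCR Gene Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a codon-optimized target gene into fixed-length DNA
    fragments whose junction overlaps are selected by nearest-neighbor melting
    temperature so that all overlaps cluster tightly around a common annealing
    temperature. Screens a range of candidate annealing temperatures, designs
    full-length gene primers, emits all-sense and alternating sense/antisense
    oligo sets, partitions fragments into balanced assembly blocks with derived
    block primers, and verifies every design by in-silico overlap-extension
    assembly. Includes a command-line interface that writes the fragment
    tables, primer table, Tm scatter plot and a machine-readable design export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
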