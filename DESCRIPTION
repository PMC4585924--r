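Package: plastidcomp
Title: Comparative Analysis of Reduced Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the compact plastid genomes of closely
    related photosynthetic and non-photosynthetic algae. Computes per-genome
    compactness statistics (size, AT content, non-coding fraction, intergenic
    spacing, inverted repeats), name-based gene-content comparison, circular
    signed gene-order synteny and breakpoint distances, deletion-junction
    characterization (AT content, tRNA adjacency), protein-guided codon
    alignment with Nei-Gojobori (1986) Ks/Ka estimation, and generation-based
    divergence-time inference. Includes a synthetic genome-pair evolver with
    known substitution and deletion truth so every analysis stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
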