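Package: selclust
Title: Clustering Tests for Positively Selected Sites in Paralogous Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests for whether amino-acid sites under positive selection in
    two paralogous proteins are differentially clustered, in the linear
    alignment and on a shared three-dimensional structure. Provides a
    parametric multi-category runs test with a bootstrap null, a
    plane-of-best-fit partition chi-square test of site placement on a
    C-alpha structure, and a nearest-selected-site paralog-affiliation
    chi-square test, together with PDB/alignment/site-list input handling,
    alignment-column-to-residue mapping, and a synthetic-data generator for
    structures, alignments and site sets so the whole pipeline can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
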