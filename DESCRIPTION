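Package: t6sscan
Title: Quorum-Based Detection, Gene-Neighborhood Graphs, Crosslink
    Validation and Stoichiometry for Type VI Secretion Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects multi-gene secretion systems in annotated bacterial
    genomes from component hits using quorum and co-localization rules
    (mandatory/accessory components, minimum gene counts, a maximum
    inter-gene distance, optional multi-locus pooling), with emphasis on
    the Bacteroidota-specific type VI secretion system (T6SS-iii) and its
    TssNQOPR membrane complex. Summarizes locus organization across
    genomes as a weighted component-contiguity graph, validates predicted
    protein structures against crosslinking mass-spectrometry restraints
    (Calpha-Calpha distances at a 35 Angstrom threshold), estimates
    complex stoichiometry from spectral counts via the exponentially
    modified protein abundance index (emPAI), and computes bacterial
    competition assay metrics. Seeded simulators generate annotated
    genomes with implanted loci, self-avoiding Calpha chains with
    crosslink sets of controlled composition, and peptide counts from
    known copy numbers, each with machine-readable ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    rtracklayer,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
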