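Package: panlin
Title: Bacterial Pangenome Partitioning, Genome Identity Metrics and
    Lindane-Pathway Screening
Version: 1.0.0
Authors@R: person("panlin", "maintainers", email = "panlin@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics toolkit for bacterial genome collections:
    greedy incremental protein clustering with an identity threshold and
    length-difference cutoff (CD-HIT semantics), core/accessory/unique
    pangenome partitioning with a homology-based false-positive filter for
    strain-specific clusters, pangenome accumulation curves and a Heaps-law
    openness fit, fragment-based average nucleotide identity (ANIb style)
    and reciprocal-best-hit average amino acid identity, and a
    threshold-based homology screen for xenobiotic degradation pathways
    including gamma-hexachlorocyclohexane dehydrochlorinase (LinA) isoform
    typing with diagnostic residues. Ships a synthetic-data generator that
    produces pangenomes, diverged genome pairs and LinA-like variant sets
    with known ground truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
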