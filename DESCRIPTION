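Package: ConstructDesigner
Title: Design of Protein Expression Constructs, PCR Primers and Plasmid Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing truncation constructs for recombinant protein
    expression. Matches coding DNA to protein isoforms (exactly or with up to
    three single amino-acid substitutions), scans multicistronic and genomic
    nucleotide sequences for open reading frames, converts residue-level
    construct boundaries into melting-temperature-targeted PCR primers with
    ligation-independent, restriction or custom cloning overhangs, enumerates
    all start/stop construct combinations with ProtParam-style physicochemical
    properties (molecular weight, isoelectric point, extinction coefficient at
    280 nm) for bare, tagged and protease-cleaved forms, filters tabular
    homology-search hits into homolog and PDB-similarity annotation tracks, and
    writes primer/construct tables and annotated GenBank plasmid maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
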