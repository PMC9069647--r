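Package: crossBeta
Title: Geometric Parallel Beta-Sheet Detection and Boundary Prefix Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects amyloid-characteristic parallel beta-sheet segment pairs in
    protein structures from C-alpha coordinates alone, using a distance-band,
    distance-variance, curvature and chain-coverage filter; extracts the
    length-5 boundary prefixes (two flanking residues plus the first three
    strand residues) and suffixes of the detected segments; tallies their raw
    multiplicities partitioned by experimental method; and searches protein
    sequence collections for exact occurrences of these k-mers. Includes a
    generator of ideal cross-beta fibril structures and negative decoys so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
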