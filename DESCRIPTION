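Package: cleavemap
Title: Cleavage-Site Cartography for Modification-Dependent Restriction
    Endonucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates modified-cytosine genomes and their digestion by
    bipartite modification-dependent restriction endonucleases (type IV
    enzymes that cleave only 5-hydroxymethylcytosine- or glucosyl-5hmC-
    marked DNA), emulates end repair and paired-end library preparation,
    and infers the enzyme's cut-site geometry from mapped fragment ends
    alone: overhang length and polarity from the adjacent-fragment gap
    distribution, dual-strand nick coordinates, flanking-sequence base
    frequency matrices and information content, the recognition consensus,
    and the offsets of the nicks relative to the modified bases.  Also
    provides the downstream quantifications such analyses feed: base-pair
    to Angstrom span conversion for dimer-recognition geometry, coverage
    depletion ratios, and efficiency-of-plating statistics.
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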