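Package: plasbhr
Title: Plasmid Mobility Typing and Broad-Host-Range Candidate Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Homology-based characterization of plasmid sequences:
    six-frame ORF calling with bacterial translation table 11, exact
    Smith-Waterman local alignment with Karlin-Altschul E-values against
    category-tagged reference protein and nucleotide panels, rule-based
    mobility classification (conjugative, mobilizable, non-mobilizable)
    from relaxase, type IV secretion system and oriT evidence, MOB/MPF/Inc
    type assignment, five-feature broad-host-range candidate selection
    (toxin-antitoxin pairs, partitioning, SOS inhibition, mating-pair
    stabilization, methyltransferases), fragment-based average nucleotide
    identity clustering at 95 percent, and nonparametric cohort statistics
    (Kruskal-Wallis with Dunn's post hoc test). Includes a synthetic
    plasmid cohort simulator with planted, machine-readable ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
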