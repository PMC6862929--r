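Package: chaingapfill
Title: Fill Repeat-Masked Gaps in Pairwise Genome Alignment Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unaligned regions bounded by co-linear alignment blocks in
    pairwise genome alignment chains (UCSC chain format), re-aligns them with a
    built-in seed-and-extend local aligner that also uses repeat-overlapping
    seeds, combines the new local alignments into a best co-linear mini chain
    under piecewise-linear gap costs, and splices qualifying mini chains back
    into the parent chains. Ships a synthetic genome-pair simulator (planted
    repeat families, lineage divergence, soft-masking, ground-truth orthology
    map and a first-pass chain computed under a repeat-masked seeding regime)
    so the whole method can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
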