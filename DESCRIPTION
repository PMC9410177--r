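Package: lignanscreen
Title: Pan-Genome Peroxidase/Laccase Census and Pinoresinol Synthase
    Candidate Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes peroxidase (POD) and laccase (LAC) gene families
    across a crop pan-genome and prioritizes candidate (+)-pinoresinol
    synthase genes by a multi-stage expression screen anchored to the seed
    lignan accumulation kinetic. Provides HMMER domain-hit filtering and
    domain verification, similarity-graph orthogrouping with
    core/shared/specific classification, MCScanX-style collinear block
    chaining with tandem/segmental duplicate classification, the
    seed-preference / early-expression / seed-color / kinetic-concordance
    candidate filters, promoter cis-element scanning with hypergeometric
    transcription-factor enrichment, 2^-ddCt relative expression, and a
    synthetic pan-genome generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
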