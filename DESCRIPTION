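Package: phantax
Title: Active Microbial Community Designation from Paired 16S rRNA and
    rRNA-Gene Amplicon Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designates transcriptionally active bacterial taxa from paired
    16S rRNA (cDNA) and 16S rRNA-gene (DNA) amplicon count tables using the
    phantom-taxon adjustment and an rRNA:rRNA-gene ratio threshold, and
    classifies reactivation, persistence, and treatment-specific enrichment
    of taxa in before-after-control-impact (BACI) soil mesocosm time series.
    Includes a paired DNA/cDNA community simulator with known ground-truth
    activity dynamics, preprocessing (pairing, rarefaction, contaminant and
    organelle filtering), a simplified negative-binomial Wald contrast for
    differential abundance, and first-principles community statistics
    (Bray-Curtis, permutation PERMANOVA, PCoA, partial constrained
    ordination, diversity indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
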