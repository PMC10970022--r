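Package: fpfinder
Title: Fingerprint Genomic Site Detection by TF-IDF Scoring of Variant Presence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "fingerprint" genomic sites that are frequent within a
    target sub-population (a breeding pedigree, or cultivars from one
    geographic region) yet rare in a background cohort. Variant calls from a
    multi-sample VCF are converted to a presence/absence matrix, each site is
    scored by term frequency times inverse document frequency (TF-IDF), and a
    permutation-simulated null distribution supplies the selection threshold.
    Includes region-specific scanning across geographic sub-populations,
    genic-context annotation of sites against GFF3 gene models, a
    down-sampling test for gene-related enrichment, and a synthetic-cohort
    simulator with planted fingerprint sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
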