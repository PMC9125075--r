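Package: haplomark
Title: Haplotype Classification and Intragenic Marker Design for
    Gene-Based Selection in Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns multi-accession gene-locus sequences into deployable
    genotyping assays.  Extracts a fixed analysis region around each gene
    (2-kb upstream flank, coding region, 1-kb downstream flank), aligns
    panel accessions to a reference, calls SNPs and indels with
    ATG-relative coordinates, and groups accessions into named haplotypes
    with an elite designation.  Candidate diagnostic variants are then
    converted into concrete PCR assays through a prioritized cascade
    (Indel, then CAPS, then dCAPS, then PARMS allele-specific primers),
    with in-silico PCR and restriction digestion to validate each
    marker's discriminating power, and panel scoring utilities that
    count elite haplotypes per accession and summarize their
    distribution across subpopulation groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
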