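Package: zwseeker
Title: Sex-Determining Region Discovery and W-Linked Marker Development for ZW Teleosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to localize a sex-determining region (SDR) from a sexed,
    low-coverage resequencing cohort and to develop a PCR-based sexing assay
    around a W-linked structural variant. Includes a seeded cohort simulator
    with allelic-depth aware genotype calls, assembly scaffold curation by
    k-mer containment, single-marker association scans with permutation
    thresholds and KNN genotype imputation, heterozygosity-ratio
    classification of ZW versus XY heterogamety, indel marker discovery with
    nearest-neighbor primer melting temperatures and in-silico PCR, and
    phylogenetic footprinting of conserved promoter motifs with
    position-weight-matrix scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
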