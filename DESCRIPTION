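Package: autozyg
Title: Autozygosity Mapping and Recessive Candidate Variant Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping fully penetrant recessive disease variants in
    small inbred pedigrees: marker quality control, single-point parametric
    linkage under a recessive disease model (Elston-Stewart style peeling),
    run-of-homozygosity detection with allelic sharing across cases,
    critical-interval intersection and gap-tolerant merging, Mendelian
    segregation filtering of multi-sample variant calls, transcript-aware
    consequence annotation with HGVS naming, and an exact allele-balance test
    for nonsense-mediated decay. A gene-dropping simulator generates pedigree
    array genotypes, case/carrier/control variant tables, transcript fixtures
    and allele counts with known ground truth, so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
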