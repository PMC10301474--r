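Package: starshift
Title: Resolving Duplicated CYP2D6 Star Alleles from Real-Time PCR Signal Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines which CYP2D6 star allele is duplicated in samples with a
    full-gene duplication by quantifying the allelic-ratio shift of heterozygous
    TaqMan endpoint genotyping signals relative to two-copy comparator clusters,
    combined with three-probe (promoter, intron 6, exon 9) copy-number data.
    Ambiguous evidence is routed to reflex sequencing rather than forced into a
    call. Includes a seeded generative model of endpoint signals and copy-number
    estimates (with allelic dropout and control-gene interference), integer
    enumeration of hybrid-gene structures consistent with the three-probe copy
    estimates, CPIC/DPWG activity-score and metabolizer-phenotype translation,
    and a command-line interface over TSV/JSON inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
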