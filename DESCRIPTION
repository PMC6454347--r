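Package: gcdm
Title: Genomic Common Data Model for Clinical Sequencing Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Relational common data model for clinical next-generation
    sequencing variant data, extending an OMOP-style clinical schema with
    genomic test, target gene, variant occurrence and variant annotation
    tables. Provides HGNC gene-symbol canonicalization, HGVS protein
    nomenclature parsing with three-letter residue enforcement and Xaa
    wildcard matching, ETL from MAF and annotated VCF files, cohort
    profiling (demographics, per-gene variant frequencies, variant-type
    proportions, actionable-mutation frequencies, waterfall matrices),
    privacy-preserving aggregate export with small-cell suppression, and
    two-site comparison with chi-squared tests. Includes a synthetic cohort
    generator emulating a targeted cancer-panel site and a WES-restricted
    site for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
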