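Package: lohmapr
Title: Mapping Parental-Allele Loss Patterns Across Multifocal Tumors
Version: 0.1.0
Authors@R: person("lohmapr", "maintainers", email = "lohmapr@example.org", role = c("aut", "cre"))
Description: Maps somatic loss of heterozygosity (LOH) from tumor/normal
    allelic read depths. Identifies germline heterozygous SNPs from normal
    read counts, tests each SNP in each tumor for allelic imbalance with an
    exact binomial test against 0.5, controls the false discovery rate with
    the Benjamini-Hochberg step-up procedure, assigns the retained parental
    allele at every LOH-informative SNP, and classifies the cross-tumor
    pattern of parental-allele loss in multifocal tumors (same allele,
    opposite alleles, or arm-discordant loss on a target chromosome). Also
    provides a simplified binned read-depth log2-ratio screen for hemizygous
    chromosome loss, and a synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
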