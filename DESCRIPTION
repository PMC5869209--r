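Package: kiwisat
Title: Noninvasive Microsatellite Genotyping and Monitoring for Kiwi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for noninvasive genetic monitoring of kiwi (Apteryx spp.)
    with a panel of 22 autosomal microsatellite loci and the Z37B sex-linked
    marker. Implements multi-tube consensus genotyping from replicated PCR
    amplifications with the consensus quality index (QI), GIMLET-style
    estimation of amplification failure, allelic dropout and false-allele
    rates, population diversity statistics (allele counts, private alleles,
    expected and observed heterozygosity, FIS), per-locus and cumulative
    probability of identity (PI and PIsibs), fragment-size sex determination
    for the ZW system, genotype matching for individualization, principal
    coordinates analysis on the codominant genotypic distance, and qPCR
    standard-curve quantification with delta-Cq inhibition assessment. A
    synthetic-data generator produces populations, true genotypes, replicated
    amplifications and qPCR plates with the statistical structure the
    analysis assumes, so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
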