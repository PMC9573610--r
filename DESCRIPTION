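Package: peaheat
Title: Heat-Tolerance Screening and Marker Diversity Analysis for Pea Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for field-based heat-tolerance screening of pea (Pisum
    sativum) germplasm panels and for SNP-marker diversity and population
    structure analysis of the screened accessions. Implements the
    grain-weight loss-rate classifier (nine tolerance levels with an
    exclusion rule), iterative multi-round screening with consistency
    tracking, growth-window thermal summaries (heat-stress day counts and
    degree-day accumulation), per-marker diversity indices (MAF, gene
    diversity, observed and expected heterozygosity, Botstein PIC),
    allele-sharing and Nei (1972) genetic distances, UPGMA trees, principal
    coordinate analysis, a STRUCTURE-style admixture Gibbs sampler with
    Evanno delta-K model selection, SNaPshot primer design-rule validation,
    and seeded synthetic generators for temperatures, field trials and
    genotype matrices so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
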