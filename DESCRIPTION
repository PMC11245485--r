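Package: stresshub
Title: Identification of Hub Stress-Responsive Transcription Factors by
    Integrated Network and Population-Genetic Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for nominating hub
    stress-responsive transcription-factor genes (e.g. rice NACs) from
    multi-omic evidence. Differentially expressed genes under abiotic stress
    are clustered by independent component analysis, per-cluster regulatory
    networks are inferred by tree-ensemble importance with transcription
    factors as candidate regulators, and hub regulators are then filtered
    genetically: kinship-aware mixed-linear-model association of regional
    variants with drought-tolerance traits, linkage disequilibrium, windowed
    nucleotide diversity contrasted between wild and cultivated groups
    (selective sweeps), and precipitation-linked geographic distribution of
    the associated alleles. A synthetic-data generator with planted ground
    truth (hub-driven co-expression programs, two-level population structure,
    a causal promoter variant, a low-diversity sweep region and a
    precipitation cline) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
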