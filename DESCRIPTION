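Package: epiradkit
Title: Presence/Absence DNA Methylation Inference from Paired RAD/EpiRAD Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers binary DNA methylation states from methylation-sensitive
    reduced-representation sequencing (EpiRADseq) read counts: counts-per-million
    standardization, locus retention filtering, zero-read methylation calling,
    per-sample methylation proportions, shared-locus accounting across sample
    groups, classical multidimensional scaling of binary methylation patterns,
    and a small-sample (AICc) linear-model selection layer for age and sex
    effects applied to methylation proportions and telomere-length medians.
    Includes a synthetic-data generator that emulates paired RAD/EpiRAD
    libraries with known ground-truth methylation states and fin-gonad
    telomere structure, so the full analysis is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
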