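Package: cryofil
Title: Single-Cell F-Actin Quantification and Cryopreservation Damage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the F-actin cytoskeleton of single adherent cells from
    per-filament measurements (length, width, orientation) via three descriptors
    (circular standard deviation, F-actin content, mean filament length), scores
    paired pre/post-cryopreservation alterations, assigns apoptosis-gated damage
    classes (I/II/III/detached), and summarises cohorts with class fractions and
    rank tests. Includes a synthetic-cohort generator with phenomenological
    cryo-damage operators (buckling, depolymerization, cracking), a fluorescence
    renderer, and a simplified filament extractor for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
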