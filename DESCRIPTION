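Package: satdrive
Title: Satellite-Array Editing, Target-Site Survival and Meiotic-Drive Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying CRISPR manipulation of pericentromeric satellite
    DNA arrays such as the Drosophila melanogaster Responder (Rsp) locus.
    Represents a satellite locus as an ordered, annotated array of repeat units,
    transposable-element islands and flanks; classifies and counts repeat copies
    from alignment hits; searches sequences for guide-RNA target sites (PAM-aware,
    with mismatches) and measures target-site survival between parent and edited
    alleles; simulates multi-cut deletion and expansion outcomes under explicit
    end-joining repair rules; infers recombination breakpoints from windowed
    allele-depth-ratio genotype states in variant tables; and computes
    viability-corrected meiotic-drive strength (k) with exact tests. A seeded
    synthetic-data module generates arrays, variant tables and cross counts with
    known truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
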