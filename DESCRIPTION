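Package: clonetrackr
Title: Clonal Expansion Analysis for T-Cell Receptor Beta Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying clonal expansion in TCR-beta repertoires
    from bulk 5'-RACE sequencing and single-cell samples: expanded-clone (EC)
    calling at frequency thresholds, shared-clone rates between compartments,
    FACS-size-corrected distribution of clones across CD4+ T-cell subsets,
    longitudinal and cross-tissue clone tracking with mEC/EC/NEC
    classification, a Hamming-distance error-correction stage with
    truth-based evaluation, and a synthetic repertoire generator with
    power-law clone sizes, PCR amplification bias and per-base substitution
    error for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
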