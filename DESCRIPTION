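Package: clonetracer
Title: Longitudinal Tumor Subclone Tracking from Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for following the subclonal composition of tumors across
    sequential treatment timepoints from somatic mutation read counts and
    allele-specific copy-number segments. Implements purity- and
    copy-number-corrected relative variant allele fractions (rVAF),
    threshold-based somatic call emulation with sub-threshold trace-read
    rescanning, multi-sample clonal clustering by a finite binomial-mixture
    model with BIC model selection, singleton-merge and small-cluster pruning
    rules for display, tumor mutational burden and substitution-spectrum
    summaries, cohort-level copy-number-alteration dynamics, clinical response
    classification (RECIST and UICC product rule), mutation-response
    association scans, and a synthetic longitudinal cohort generator with a
    known clonal ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
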