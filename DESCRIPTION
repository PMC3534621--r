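Package: sgtkit
Title: Start Growth Time Analysis of Microplate Growth Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies viable bacteria from kinetic OD600 microplate data
    using the Start Growth Time (SGT) statistic: the time a regrowing
    culture takes to cross a fixed absorbance threshold, which is linear in
    the log of the starting live-cell inoculum. Provides threshold-crossing
    detection with interpolation and censoring, a qPCR-style
    delta-delta-SGT relative-survival calculus with error propagation,
    linear SGT-versus-log10(CFU/mL) calibration with inverse prediction,
    end-to-end antibiotic-tolerance (persister) assay workflows, a seeded
    logistic-growth plate simulator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
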