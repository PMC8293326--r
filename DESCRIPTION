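Package: rulerbench
Title: Benchmarking Proteomics Method Sensitivity with Absolute Protein
    Copy Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares shotgun-proteomics methods by the absolute copy
    numbers of the proteins they identify rather than by raw
    identification counts. Builds copies-per-cell reference tables from
    quantitative protein reports using the histone proteomic ruler
    (including iBAQ from in-silico tryptic digestion and average
    molecular weights from FASTA), parses MaxQuant and Proteome
    Discoverer protein reports and plain accession lists, maps
    identification lists onto a reference proteome, and summarizes each
    experiment by matched protein count, mean and median log10 copy
    number and reference coverage. Renders count- and density-normalized
    log10 copy-number histograms with apex reference lines and companion
    data tables, and ships a synthetic proteome generator (log-normal
    copy numbers, consistent quantitative signals, abundance-dependent
    detection) so the full pipeline is testable offline. A command-line
    interface exposes the pipeline as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
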