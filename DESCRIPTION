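Package: episwitch
Title: Integrative Promoter Methylome and Transcriptome Analysis for
    Drug-Induced Epigenetic Switches
Version: 1.0.0
Authors@R:
    person("Episwitch", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of two-colour MeDIP promoter tiling-array
    methylation profiles combined with expression microarray signals in a
    two-organ, two-treatment rodent study design.  Implements probe-level
    M/A-value computation, saturation filtering, per-array loess dye-bias
    correction, transcription-start-site window aggregation, median centering
    and between-array scaling, differential-methylation calling, split-plot
    analysis of variance with donor as a random effect, an expression filter
    cascade with hierarchical clustering, symbol-based pairing of expression
    and methylation with donor-level correlation tests, and locus-level
    validation-assay calculators (comparative-Ct qPCR, MeDIP- and ChIP-qPCR
    enrichment, bisulfite clone summarisation, pyrosequencing group
    comparison).  A synthetic-data module generates all pipeline inputs with
    planted ground truth for parameter-recovery testing, and a command-line
    interface ties the stages into a reproducible end-to-end run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    limma,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
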