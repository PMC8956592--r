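Package: targetprio
Title: Druggable-Genome Cross-Referencing and Drug-Repurposing Target
    Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates disease risk-gene lists from three evidence classes
    (common, rare, and expression-related genetic variation) with an
    approved-drug target-efficacy catalog, a curated clinical repurposing
    trial list, and IDG-style per-target metadata. Produces the druggable
    gene set and its evidence partition, repurposing-status labels, protein
    class distributions of genetic versus clinical-trial targets, target
    development level (TDL) classifications including the clinical
    repurposing category, and multi-axis prioritisation tables with mouse
    neurophenotype scoring and shortlists of underexplored targets. Ships a
    synthetic-data generator that emits all input tables together with a
    ground-truth manifest so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
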