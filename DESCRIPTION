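Package: ceascreen
Title: Cost-Effectiveness Analysis of Colorectal Cancer Screening Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-arm cost-effectiveness evaluation of colorectal cancer
    screening from the healthcare provider perspective, comparing germline
    genetic testing against immunological faecal occult blood testing
    (iFOBT). Provides provider costing (top-down and activity-based, with
    currency conversion), EQ-5D-5L utility scoring against pluggable value
    sets, stage-wise life-year and quality-adjusted life-year (QALY)
    construction from stage-specific mean survival, incremental
    cost-effectiveness ratios (ICER) with cost-effectiveness-plane
    dominance classification and GDP-per-capita threshold bands, and
    deterministic discount-rate sensitivity analysis. Ships a bundled
    two-arm study dataset and a synthetic patient-level cohort generator
    so every stage of the pipeline is reproducible and testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
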