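Package: omicsweave
Title: Integration of Serum Metabolome, Blood Transcriptome and miRNome
    into Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-omic integration of paired
    two-timepoint cohorts: NMR metabolite peak filtering and assignment,
    discriminant chemometrics (PCA, interclass PCA with Monte-Carlo
    testing, OPLS with orthogonal signal correction, cross-validation and
    permutation validation), paired differential expression with
    Benjamini-Hochberg control, metabolite-to-metabolic-gene enrichment
    (hypergeometric and rank-sum), miRNA target overlay, regulatory
    impact factor (RIF) scoring of candidate regulators, pathway
    topology impact, and multiple factor analysis (MFA) with RV
    coefficients for cross-table validation. Includes a synthetic cohort
    generator with planted, ground-truthed differential and
    co-expression structure for calibration and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
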