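Package: glycosens
Title: Differential N-Glycosylation Site Occupancy and Multiplicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for label-free glycoproteomics of mild N-glycosylation
    defects. Scans protein sequences for N-glycosylation sequons (N-X-S/T,
    X != Pro), builds an evidence-based reference glycoproteome from
    deglycosylated-peptide detection patterns, applies detection-pattern
    filters and paired/unpaired differential tests to total-proteome and
    glycosite intensity tables without imputation, cross-references decreased
    glycosites against unmodified-peptide evidence to call occupancy loss, and
    quantifies susceptibility determinants: glycoprotein enrichment among
    decreased proteins, N-glycan multiplicity effects, sequon-position motif
    enrichment (aromatic -2, Ser +2) and the NxS-fraction-versus-multiplicity
    correlation. Includes a synthetic glycoproteome generator with
    intensity-dependent (missing-not-at-random) dropout so every stage is
    testable without deposited mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
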