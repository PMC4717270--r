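Package: turnoverMS
Title: Protein Turnover Kinetics and Differential Abundance from
    Heavy-Label Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for stable-isotope (2H3-leucine) metabolic
    labeling proteomics. Simulates diet-switch labeling studies with known
    ground truth; deconvolves peptide isotopologue envelopes into the
    fraction of newly synthesized protein while estimating precursor-pool
    enrichment; fits first-order turnover kinetics with peptide blocking
    factors and computes half-lives; compares turnover rates between
    experimental groups by ANCOVA; computes differential protein abundance
    from peptide areas with false-discovery-rate control; and produces
    compartment-stratified half-life summaries, change classifications,
    and gene-set enrichment reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
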