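Package: migdr
Title: Stool-Phenotype-Stratified Analysis of Urinary Uremic Toxins and the
    MIGD/OGI Composite Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing creatinine-normalized urinary uremic toxin
    panels (p-cresyl sulfate, indoxyl sulfate, trimethylamine N-oxide,
    asymmetric and symmetric dimethylarginine) stratified by Bristol Stool
    Chart phenotype. Computes the component toxin ratios PCS/TMAO and IS/ADMA
    and the composite Metabolic Index of Gut Dysfunction (MIGD, also called
    the Osredkar-Godnov Index), in both group-level (median-based) and
    individual-level modes, with interpretation bands, tie-corrected
    Kruskal-Wallis group comparisons under Benjamini-Hochberg false discovery
    rate control, noncentral-t sample-size calculation, and a seeded
    log-normal synthetic cohort generator calibrated to published quartile
    summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
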