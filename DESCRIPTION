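Package: methylosip
Title: RNA Stable Isotope Probing Label Calling and Radiotracer Methanol
    Turnover Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies 13C-labelled methanol-utilizing taxa from RNA
    stable isotope probing (SIP) density-gradient fraction abundance
    tables using three enrichment criteria (heavy-fraction abundance above
    the 12C control, heavy-to-light enrichment by a factor K, and a
    minimum heavy-fraction abundance floor), and estimates potential
    methanol consumption rates from 14C-methanol radiotracer trap time
    series by linear regression of cumulative trapped 14CO2 activity.
    Includes refractometry-to-buoyant-density conversion and heavy/light
    fraction classification, trap mass-balance and BaCO3 cross-check
    quality control, delta-13C two-point VPDB normalization, OTU-table
    diversity summaries (singleton removal, Shannon, Chao1, analytic
    rarefaction, Michaelis-Menten asymptotic richness, Bray-Curtis
    dissimilarity), and a synthetic-data generator producing gradient
    experiments and trap series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
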