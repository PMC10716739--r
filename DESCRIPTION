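Package: ctraitkit
Title: Carbon-Preference Traits and H2 Oxidation Analysis for Soil Microcosm Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for carbon-amendment soil microcosm experiments
    probing high-affinity H2-oxidizing communities. Estimates significance-gated
    H2 oxidation rates from static-headspace gas chromatography time series,
    performs ASV-table quality control (relative-abundance and prevalence
    filters, library-size bias check, centered log-ratio transformation with a
    non-negativity shift), places amplicon sequence variants on a ternary
    carbon-preference simplex (C-ness, St-ness, Su-ness) gated by a
    compositional differential-abundance test, computes Hill-number alpha
    diversity with asymptotic estimators, and runs permutation-based community
    statistics (Bray-Curtis on Hellinger-transformed counts, PCoA, two-factor
    PERMANOVA with pairwise comparisons). Includes a synthetic-data generator
    with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
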