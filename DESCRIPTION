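Package: dspattenuate
Title: Attenuation of Spaceflight Transcriptomic Signatures in Digital
    Spatial Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for GeoMx-style digital spatial profiling
    count data from a 2x2 spaceflight-by-antioxidant mouse brain study.
    Implements third-quartile (Q3) normalization, per-region unpaired
    t-test differential expression with permutation-based q-values,
    direction-concordance statistics for antioxidant attenuation of
    flight-induced expression changes (contingency table with Fisher's
    exact test and a gene-shuffling permutation null), ANOVA-filtered
    principal component analysis with group-centroid distances, local
    hypergeometric over-representation analysis, and a negative-binomial
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
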