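Package: gastroclone
Title: Clonal Dynamics and Somatic Mutation Analysis of Microdissected Gastric Glands
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mutations in laser-capture microdissected gastric
    glands sequenced at moderate depth. Implements post-calling variant filters
    (alignment-quality thresholds, exact binomial germline test, beta-binomial
    overdispersion artifact filter), truncated binomial mixture modelling of
    variant allele fractions with sensitivity-corrected mutation burdens,
    mixed-effects mutation-rate models, mutational-signature exposure fitting and
    metaplasia fold-increase analysis, molecular timing of copy-number gains,
    haplotype-phased trisomy detection in targeted panel data, and estimation of
    the epithelium fraction colonized by driver-mutant clones. Includes a
    synthetic cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
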