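Package: recalv
Title: Recursive Threshold Mixed Models for Calving Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian multi-trait sire-maternal-grandsire models for three
    calving traits: gestation length (continuous), calving difficulty and
    stillbirth (ordinal, modelled on the liability scale with threshold
    links). Supports a standard mixed model with unstructured covariance
    matrices and a family of recursive (structural equation) mixed models in
    which gestation length affects the liabilities to calving difficulty and
    stillbirth, and liability to calving difficulty affects liability to
    stillbirth, with structural coefficients that change across categories of
    gestation length. Inference is by Gibbs sampling with liability
    augmentation; the package also provides reduced-form covariance
    transformations, Willham-type direct and maternal genetic parameters,
    posterior summaries (HPD intervals, Monte Carlo errors, split R-hat),
    goodness-of-fit and cross-validated predictive-ability comparisons, and a
    synthetic-data generator with the record structure of national
    calving-ease programme data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
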