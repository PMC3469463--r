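Package: famliab
Title: Liability-Threshold Models Comparing Family History and SNP-Based
    Disease Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the predictive accuracy of family-history-based,
    SNP-based, and combined risk-prediction models for polygenic disease
    under the liability threshold model. Assembles joint liability
    distributions over pedigrees, computes disease-status pattern
    probabilities by multivariate-normal integration, and derives ROC
    curves, AUC, predictive values, and likelihood-ratio distributions
    for complete and restricted family-history classifiers. Provides
    closed-form accuracy for SNP-based models explaining a given
    fraction of heritability, the inverse "equivalent heritability
    explained" mapping, conditional-Gaussian combined models, estimation
    of heritability explained by lists of SNP associations with
    winner's-curse correction, and a Monte-Carlo simulator used as an
    independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
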