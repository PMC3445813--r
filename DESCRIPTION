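Package: lbadecide
Title: Linear Ballistic Accumulator Models of Voluntary Action Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits constrained families of linear ballistic accumulator (LBA)
    models to choice and specified finger-tapping behaviour. Provides a
    six-feature model design space, stochastic forward simulation of the
    race process, quantile-based likelihood-ratio chi-square (G-squared)
    fitting by multi-restart Nelder-Mead, BIC model selection across
    participants with nonparametric post-hoc tests, closed-form trial-wise
    expected accumulated activity (EAA) for model-based fMRI parametric
    regressors, and a synthetic task and behaviour generator with parameter
    and model recovery harnesses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
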