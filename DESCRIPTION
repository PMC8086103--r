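Package: deltameth
Title: Estimand-Correct Effect Estimates for Differential DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reporting biologically interpretable effect sizes in
    differential DNA-methylation analysis. Implements the exact transformation
    algebra between array intensities, Beta-values and M-values, the intercept
    method that converts M-scale regression coefficients into
    confounder-adjusted differences in Beta-values, the non-bijective
    ("mustache") envelope linking M-value differences to attainable Beta-value
    differences, four per-CpG estimation approaches (Gaussian regression on
    Beta-values, beta regression, raw Beta-value mean differences with M-scale
    p-values, and M-value regression with intercept retrieval), and simulation
    machinery that quantifies the bias of each reporting approach under
    group-imbalanced confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
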