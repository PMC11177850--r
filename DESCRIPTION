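Package: neoscr
Title: Population Kinetics of Serum Creatinine in Cooled Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic population model of time-dependent serum creatinine
    (sCr) in (near)term neonates treated with therapeutic hypothermia for
    hypoxic-ischemic encephalopathy. Implements the structural back-flow plus
    sigmoidal-Emax GFR maturation model with lognormal between-subject
    variability, a Laplace marginal-likelihood estimator with empirical Bayes
    estimates, shrinkage and standard errors, forward-inclusion
    backward-elimination covariate selection by likelihood-ratio test,
    conditional weighted residual and visual-predictive-check diagnostics,
    cohort trajectory simulation, and a synthetic longitudinal-data generator
    emulating the study cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
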