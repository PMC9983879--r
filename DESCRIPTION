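Package: magreml
Title: Mediation Analysis with Genome-Based Restricted Maximum Likelihood
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the extent to which a mediator trait transmits the
    additive SNP-based genetic component of an outcome trait. Fits a
    bivariate variance-component model by restricted maximum likelihood
    (GREML), with the genomic relatedness matrix (GRM) as the covariance
    model of the latent genetic factors, and maps the six variance
    components onto the effect of the mediator on the outcome, the
    genetic variance of the outcome mediated by the mediator (indirect
    effect) and the genetic variance not mediated (direct effect), with
    delta-method standard errors. Significance of the indirect effect is
    assessed with a likelihood-ratio test whose null parameter space is
    the union of "mediator has no genetic variance" and "mediator has no
    effect on the outcome", with degrees of freedom chosen by where the
    null optimum is attained. Includes GRM construction from dosage data,
    GCTA-format GRM input/output, relatedness pruning, a structural
    simulation module for power and calibration studies, and a GREML
    power calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, methods
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
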