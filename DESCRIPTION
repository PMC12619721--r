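Package: pmipf
Title: Post-Mortem Interval Estimation from Pericardial-Fluid NMR Metabolomics
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for estimating the post-mortem interval (PMI)
    from 1H-NMR metabolite concentration tables of human pericardial fluid.
    Implements age-constrained projection to latent structures regression
    (oCPLS2) and classification (oCPLS2C) fitted by NIPALS, variable influence
    on projection (VIP) scores, stability selection by binary matrix sampling,
    repeated k-fold cross-validation with Q2/SDECV, response-permutation
    tests, cluster-representative training-set extraction, univariate screens
    (age-corrected Pearson, FDR-controlled multiple linear regression,
    age-adjusted logistic regression), two-batch cosine-similarity
    reproducibility assessment, and a synthetic-data generator that emulates
    the covariate and concentration structure of a two-centre autopsy study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
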