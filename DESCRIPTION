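Package: careclass
Title: Latent-Class Patterns of Children's Mental-Health Service Use
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Person-centered analysis of longitudinal service-utilization
    records from children's mental-health agencies: seeded synthetic cohort
    generation, inclusion/exclusion cohort filtering with attrition logging,
    episode-of-care segmentation of visit streams, 48-month binary trajectory
    coding, latent class analysis by EM with AIC/BIC/CAIC model selection and
    parametric bootstrap, Little's MCAR test and EM imputation of intake
    covariates, canonical discriminant function analysis with Wilks' lambda
    tests and leave-one-out cross-validation, and the descriptive pattern
    tables that summarize service use by latent class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), MASS, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
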