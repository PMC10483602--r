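Package: ctmon
Title: Longitudinal Circulating Tumour DNA Monitoring in Advanced Pancreatic Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serial plasma ctDNA monitoring of patients
    with advanced pancreatic ductal adenocarcinoma under palliative
    chemotherapy. Converts PNA-clamp qPCR replicate Cq values into delta-delta-Cq
    ctDNA levels with control-panel detection cutoffs; compares baseline
    characteristics by ctDNA status with exact contingency-table tests
    (Fisher 2x2 and Freeman-Halton r x c); provides Kaplan-Meier, log-rank and
    Cox proportional-hazards analyses with landmarking and likelihood-ratio
    backward elimination; fits a Bayesian joint model of the longitudinal
    ctDNA trajectory (natural cubic splines, random effects) and time to first
    progression with current-value, slope or scaled-area association and
    subject-specific dynamic prediction; classifies serial samples to compute
    the lead time of ctDNA-indicated progression over radiological imaging;
    and generates seeded synthetic cohorts with the same data structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
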