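Package: focmscreen
Title: Multivariate Screening of Folate One-Carbon Metabolism and
    Transsulfuration Metabolites
Version: 0.1.0
Authors@R:
    person("FOCM Screen", "Maintainers", email = "maintainers@focmscreen.org",
           role = c("aut", "cre"))
Description: Cross-validated Fisher discriminant analysis of blood metabolite
    panels from the folate-dependent one-carbon metabolism (FOCM) and
    transsulfuration (TS) pathways, with Gaussian kernel density estimation of
    cohort score distributions (least-squares cross-validation bandwidths),
    ROC/C-statistic based exhaustive and greedy metabolite subset selection,
    and Gaussian-kernel partial least squares regression of adaptive-behavior
    scores with leave-one-out cross-validated R-squared. Includes a synthetic
    cohort generator with planted discriminative and regression structure so
    the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
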