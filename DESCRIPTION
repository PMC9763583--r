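Package: gutpod
Title: Gut-Microbiome Diagnostic Models with Random-Forest POD Scores
Version: 0.1.0
Authors@R: person("gutpod", "maintainers", email = "gutpod@example.org",
    role = c("aut", "cre"))
Description: Case/control diagnostic modelling for gut-microbiome OTU tables:
    candidate-OTU screening (abundance, rank-sum, forest-importance criteria),
    cross-validated random-forest feature-count selection, per-sample
    probability-of-disease (POD) scoring, ROC/cut-off evaluation and external
    cohort validation, together with the alpha/beta-diversity statistics
    (observed OTUs, ACE, Bray-Curtis, UniFrac), ordination (PCoA, NMDS),
    ANOSIM, SparCC compositional correlation, propensity-score matching and a
    Dirichlet-multinomial synthetic cohort generator used to exercise the
    whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    jsonlite,
    yaml,
    optparse,
    biomformat,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
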