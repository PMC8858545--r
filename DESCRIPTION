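Package: socialMRS
Title: Linking In Vivo 1H-MRS Brain Metabolite Features to Mouse Social
    Behavior
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline connecting proton magnetic resonance
    spectroscopy (1H-MRS) metabolite quantifications in mouse brain to
    three-chamber social behavior. Provides a synthetic-cohort generator
    with a latent-sociability generative model, a toy linear-combination
    spectral quantifier with Cramer-Rao lower-bound (CRLB) uncertainty,
    CRLB-based quality filtering with per-group inclusion rules, derived
    metabolite ratios (tCr, Glx, Glu/GABA, NAA/tCr, PCr/tCr), a
    permutation-null Pearson correlation screen with quantile tiers,
    genotype group tests (Welch and Student t, two-way ANOVA with Sidak
    contrasts), and single-feature biomarker evaluation by simple logistic
    regression and binormal ROC curves with Hanley-McNeil confidence
    intervals and Youden-optimal cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pROC,
    yaml
Config/testthat/edition: 3
biocViews: Metabolomics, Preprocessing, StatisticalMethod, Classification
RoxygenNote: 7.3.3
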