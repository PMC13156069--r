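Package: ssep
Title: Substrate-Specific Effect Prediction for Drug Transporter Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative, substrate-dependent prediction of drug transporter
    variant activity. Curates variant-substrate relative-uptake tables, profiles
    within-variant substrate variability (span, directionality, per-transporter
    fractions), assembles blocked feature bundles (ligand physicochemical
    descriptors, mutation biophysics, protein-ligand interaction geometry,
    sequence embeddings via a provider contract, in-silico predictor scores),
    and trains multi-input feed-forward regressors with deep-mutational-scanning
    fine-tuning, grid-search hyperparameter selection and per-structure score
    integration. Includes the evaluation toolkit (Spearman, RMSE, rank error,
    activity binning, Jonckheere-Terpstra trend test, Kruskal-Wallis, ROC-AUC,
    per-substrate benchmarking), a descriptive feature-importance workflow with
    collinearity pruning and BH-FDR, a cohort association layer (daily-dose
    derivation, MAF filtering, weighted burden scores, covariate-adjusted dose
    regression, burden and SKAT-style rare-variant tests), and seeded synthetic
    generators with planted ground truth for offline end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
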