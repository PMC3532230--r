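Package: metabnorm
Title: Linear Mixed-Model Normalization and Inference for Targeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes wide-format targeted metabolomic signal tables by fitting a
    per-metabolite linear model (fixed effects only) or linear mixed model (REML) that
    partitions treatment-group effects from fixed-effect confounders such as tissue
    quantity and internal-standard signal and from random-effect block factors such as
    run day.  Normalized data are reconstructed as conditional residuals plus adjusted
    group means, so confounder effects are removed while group structure is retained.
    Downstream tools check model assumptions (Shapiro-Wilk normality, Brown-Forsythe
    equality of variance), perform Tukey HSD pairwise comparisons with Storey q-values
    and fold-change screening, build compact letter displays, and export a full suite
    of result files including residual plots, mean plots, pre/post confounder plots, a
    mean-centered heatmap with dendrograms, and a pathway-mapping spreadsheet.  A
    simulation module generates tables with known group, covariate, and block effects
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    car,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
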