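Package: alpskit
Title: DTI-ALPS Glymphatic Index, Cohort Scoring and Bootstrap Mediation
    for Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying glymphatic function in cerebral small
    vessel disease with diffusion MRI. Fits diffusion tensors from
    diffusion-weighted volumes by log-linear least squares, derives
    fractional anisotropy and axis-aligned diffusivities, places the
    paired projection/association-fiber regions of interest and computes
    the DTI-ALPS index (diffusion along the perivascular space). Scores
    neuropsychological batteries into domain z-composites, applies
    education-adjusted MMSE/MoCA diagnostic rules, and runs the group
    statistics battery (ANOVA including ANOVA from summary statistics,
    covariate-adjusted linear models with Bonferroni post hoc tests,
    Kruskal-Wallis, chi-square and Fisher exact tests, Pearson and
    partial correlation). Includes a covariate-adjusted single-mediator
    bootstrap mediation model (percentile and bias-corrected intervals)
    and a synthetic-data module that generates diffusion phantoms and
    cohort tables with a configurable mediation structure, so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
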