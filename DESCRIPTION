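Package: transprs
Title: Trans-Ancestry Polygenic and Environmental Risk Stratification for
    Colorectal Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis framework for stratifying colorectal
    adenoma-carcinoma risk with a trans-ancestry polygenic risk score (PRS)
    and a lifestyle-based environmental risk score (ERS). Provides a
    two-ancestry cohort simulator (LD-blocked genotypes, liability-threshold
    staged outcomes, lifestyle factors, censored follow-up),
    inverse-variance fixed-effects GWAS meta-analysis with heterogeneity
    filtering and genomic control, clumping-and-thresholding PRS
    construction with repeated cross-validated threshold selection,
    environmental risk scoring from binarized lifestyle factors with
    predictive-mean-matching imputation, and a screening evaluation layer:
    AUC, per-SD and decile odds ratios, top-percentile screening metrics,
    joint PRS-ERS stratification, additive interaction statistics
    (RERI, AP, synergy index), and Kaplan-Meier/Cox incidence analysis,
    together with closed-form Gaussian-liability oracles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    survival,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
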