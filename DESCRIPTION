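Package: simpomr
Title: Gene-Level Methylation Scoring and Two-Step Mendelian Randomization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the SIMPO gene-level DNA-methylation score, which
    contrasts mean methylation of gene-body probes against promoter probes
    as a per-sample t-form statistic, together with differential-methylation
    screens at the gene and probe level. Also provides a from-formula
    two-sample Mendelian randomization suite (inverse-variance weighted,
    weighted median, MR-Egger with pleiotropy intercept test, Cochran's Q
    heterogeneity, leave-one-out sensitivity) with GWAS summary-statistic
    harmonization and a two-step mediation runner, plus synthetic-data
    generators for methylation cohorts and GWAS summary-statistic triplets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
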