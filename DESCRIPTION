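Package: gutmr
Title: Two-Sample Mendelian Randomization for Gut Microbiome Exposures with
    Mediation Through Serum Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of gut
    microbiome features on disease outcomes such as chronic kidney disease:
    reading and validating GWAS summary statistics, instrument selection with
    LD clumping and strength diagnostics (F-statistics, variance explained),
    harmonization of exposure and outcome alleles including palindrome and
    proxy handling, causal estimation by inverse-variance weighting, MR-Egger
    regression and the weighted median, sensitivity analysis (Cochran's Q,
    Egger intercept, leave-one-out, funnel coordinates, MR-PRESSO), two-step
    MR mediation with bootstrap confidence intervals, a seeded
    summary-statistics simulator with known ground truth for calibration
    studies, and a screening/replication/mediation pipeline that emits
    deterministic report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
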