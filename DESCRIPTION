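Package: twosmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization (2SMR) with GWAS
    summary statistics: reading summary tables with configurable column maps,
    instrument selection (genome-wide significance filtering, LD clumping,
    exclusion screening, LD-proxy substitution, F statistics), allele
    harmonization with palindromic-variant handling, four causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode),
    heterogeneity and pleiotropy diagnostics (Cochran Q, Egger intercept,
    leave-one-out, single-SNP, funnel data), homogeneous-subset selection,
    power analysis for binary outcomes, and a synthetic two-sample GWAS
    generator with known causal truth for validation. Ships the five
    genome-wide-significant heart-failure instruments from the CVDKP
    heart-failure GWAS (GCST009541) used to assess the effect of genetically
    predicted heart failure on late-onset Alzheimer's disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
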