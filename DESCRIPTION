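Package: rewardconn
Title: FA-Weighted Reward-Network Connectomics with Imaging Genetics and Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds fractional-anisotropy (FA) weighted structural connectivity
    matrices over a 24-node reward-circuit atlas, detects group-different edges
    by covariate-adjusted permutation testing with family-wise (Bonferroni)
    correction, screens candidate SNPs for additive main and gene-by-addiction
    interaction effects on network strength, performs case-control genetic
    association (Hardy-Weinberg testing, chi-squared association, odds ratios,
    EM-based pairwise linkage disequilibrium), and tests simple mediation
    (genotype to network strength to cognition) with bias-corrected bootstrap
    confidence intervals. Ships a synthetic-cohort generator with known planted
    truth so the whole pipeline is testable without subject data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), RNifti, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
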