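Package: itraqr
Title: Regression-Based iTRAQ Quantification and Multi-Omic Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relative protein quantification from multiplexed iTRAQ
    reporter-ion data and for downstream multi-omic analysis of two-group
    (knockout versus wild-type) designs. Protein ratios are estimated by
    least-squares regression through the origin of sample-channel versus
    internal-standard reporter intensities, with isotope-impurity correction,
    automated regression-outlier removal, reporter-channel bias adjustment,
    quality filtering and technical-replicate compositing. Downstream stages
    provide empirical-Bayes moderated t-statistics with Benjamini-Hochberg
    false discovery rate control applied uniformly to transcript, protein and
    metabolite matrices, hypergeometric gene-set over-representation with
    sample-versus-background frequency reporting, and transcript-protein
    fold-change concordance. A seeded synthetic-data generator emulates the
    full study design (pooled internal standard, channel bias, outlier
    peptides, technical replicate runs) with known ground truth so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
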