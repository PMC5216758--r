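Package: genesynopsis
Title: Field Synopsis and Meta-Analysis of Candidate-Gene Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for systematic field synopses of candidate-gene
    case-control association studies: genetic-model contrasts (additive,
    dominant, recessive, carrier) from per-study genotype counts,
    per-study odds ratios with Haldane-Anscombe continuity correction,
    Hardy-Weinberg equilibrium testing in controls, fixed- and
    DerSimonian-Laird random-effects pooling with Cochran's Q, I-squared
    and tau-squared heterogeneity statistics, Egger and Begg
    publication-bias tests, leave-one-out and HWE-exclusion sensitivity
    analyses, and Venice-criteria grading of cumulative epidemiological
    evidence.  Includes a seeded simulator of multi-study case-control
    genotype data under Hardy-Weinberg equilibrium with a per-allele odds
    ratio, between-study heterogeneity and optional significance-based
    publication censoring, plus a bundled machine-readable transcription
    of a published 31-variant hepatocellular-carcinoma synopsis used for
    self-consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
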