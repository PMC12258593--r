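Package: orthodiv
Title: Cross-Species Divergence of Obesity-Induced Muscle Expression Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing obesity-induced skeletal-muscle
    transcriptional changes across pig, mouse and human. The core statistic is
    the standard deviation of empirically shrunken log2 fold changes over 1:1:1
    ortholog triples, with quantile classification into high/medium/low
    divergence classes. Supporting stages cover median-of-ratios normalization,
    TPM, a negative-binomial Wald differential-expression test, weighted
    Kolmogorov-Smirnov gene-set enrichment with permutation normalization,
    gene-family expansion/contraction flags with Fisher direction enrichment,
    PWM scanning with exact p-values and AME-style motif enrichment, promoter
    architecture features (TATA box, CpG islands, conservation profiles),
    syntenic open-chromatin usage classification with an eQTL permutation
    test, and Nei-Gojobori dN/dS. A synthetic-data generator with planted
    ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
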