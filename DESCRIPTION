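Package: fadevo
Title: Codon Usage Bias and Branch-Wise dN/dS Screens for Gene Family
    Origin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to weigh horizontal gene transfer against gene
    duplication as the origin of a gene family, built around the ciliate
    sterol C-22 desaturases as the motivating system. Implements
    PROSITE-style histidine-box motif curation, greedy identity
    clustering, EMBOSS-convention global alignment statistics, per-gene
    codon usage bias measures (RSCU, GC3s, Wright's effective number of
    codons, parity rule 2, neutrality regression, RSCU principal
    components), a parametric HGT screen, Nei-Gojobori (1986) pairwise
    and branch-wise dN/dS estimation on parsimony-reconstructed
    ancestors, and a GY94-style codon substitution simulator that
    supplies synthetic inputs of known ground truth (AT-rich genomes,
    GC-shifted alien gene sets, duplication scenarios with a relaxed
    post-duplication stem).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
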