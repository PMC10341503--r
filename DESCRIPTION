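Package: txeffort
Title: Transcription Effort Analysis for Bulk Expression Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools to quantify how a transcriptome's output is distributed
    across genes. From a gene-by-sample count matrix, computes per-million
    normalization, per-gene and per-group transcription effort (the
    percentage of a sample's total transcription attributable to a gene or
    gene group), ranked cumulative-effort concentration curves with
    logarithmic least-squares fits, KOG functional-category and gene-set
    (pathway, secondary-metabolite cluster, aroma gene) effort
    decompositions, and pairwise condition comparisons with a twofold-limit
    outlier rule. Includes a calibrated generator of synthetic heavy-tailed
    transcriptomes (lognormal body plus truncated Pareto tail) with paired
    conditions, planted outliers, and annotation/gene-set structure, so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
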