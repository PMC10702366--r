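Package: phosmotif
Title: Kinase Motif Inference for TMT Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative phosphoproteomics with
    isobaric (TMTpro) reporter quantification: isotopic impurity correction,
    PSM quality filtering, protein collapse, equal-loading and
    phospho-to-protein normalization, per-site differential statistics
    (Welch t, Benjamini-Hochberg FDR) with regulated/unregulated tiering,
    position-specific scoring matrix (PSSM) kinase-substrate prediction with
    percentile ranking and top-k calls, per-kinase motif enrichment
    (one-sided Fisher with dual-side exclusion), and pLogo-style binomial
    motif statistics. Includes a synthetic-data generator with spiked kinase
    effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
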