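Package: trioscan
Title: Cis-QTL Scanning and Causal Inference Testing for
    SNP-Methylation-mRNA Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative multi-omics mapping of methylation-mediated
    genetic effects on gene expression. Provides cis-window quantitative
    trait locus scans for three omics pair types (meQTL: SNP-CpG, eQTM:
    CpG-transcript, eQTL: SNP-transcript) with covariate-adjusted linear
    regression and Benjamini-Hochberg FDR control, assembly of
    SNP-methylation-mRNA trios from the significant pair sets, a
    four-condition causal inference test (CIT) with a permutation
    equivalence test for conditional independence, two-locus linkage
    disequilibrium estimation via EM over unphased genotypes, descriptive
    characterization of scan output (CpG-category breakdowns, distance
    profiles, quantile-quantile data), and export of the signed
    tripartite regulatory network.  A synthetic multi-omics generator
    with planted trio architectures (mediation, common cause, reverse
    causation, null) supplies ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
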