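Package: poolvar
Title: Pooled-Population Variant Detection for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("poolvar", "developers", email = "poolvar@example.org", role = c("aut", "cre"))
Description: Detection of SNPs, small indels and structural-variant evidence
    in pooled (population) resequencing data from experimental evolution,
    down to allele frequencies of 5 percent. Provides a likelihood-based
    pooled SNP caller over a haplotype-number frequency grid, count-based
    indel calling, automated false-positive filters (strand-biased mismatch
    context, read-position enrichment, proximity to large-indel signatures),
    founder subtraction, discordant-pair structural-variant evidence with
    soft-clip breakpoint refinement, coding-consequence annotation, and a
    paired-end read simulator with planted variants and injectable artifact
    classes for end-to-end validation of false-positive and false-negative
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
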