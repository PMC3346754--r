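Package: bsrseq
Title: Bulked Segregant RNA-Seq Mapping of Causal Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps recessive causal mutations from pooled RNA-Seq of segregating
    F2 populations (BSR-Seq). Provides de novo SNP discovery from per-pool
    allele pileups with stringent quality filters, a two-stage empirical
    Bayesian statistic for the probability that each SNP is in complete
    linkage with the causal locus, a sliding-window genome scan that reports
    the peak interval, and Fisher-exact differential expression between pools.
    A full F2 bulked-segregant simulator (Haldane-model meiosis, pool
    construction, binomial read sampling with allele-specific expression skew)
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
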