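Package: evoprofiler
Title: Evolutionary Feature Profiling of Gene Families
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative evolutionary profiling of gene families from
    multispecies orthology data. Computes a suite of eighteen per
    orthologous-group (OG) metrics covering taxonomic spread (AGE, UNI),
    copy-number dynamics (DUP, ACN, CNV, EXP, CON, STA), genomic
    organization (SYN), protein divergence (EVR), codon-level substitution
    rates via a Nei-Gojobori dN/dS estimator (PDS, PDN, SEL), population
    variation (NSP, NSD, SSD) and whole-genome alignment conservation
    (WGA, PHC). Aggregates OG metrics into per-family profiles with
    delta-mean statistics, Wilcoxon and permutation significance tests,
    clusters family profiles under four distance and four linkage methods
    with multiscale-bootstrap approximately unbiased (AU) support and a
    normalized family subtree co-occurrence score, quantifies family
    coexpression on a toroidal clustered expression map with permutation
    nulls, and pairs evolutionary with expression similarity. A
    synthetic-data module generates every pipeline input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
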