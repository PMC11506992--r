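Package: genotracks
Title: Integrated Chromosome-Track Visualisation of GWAS, Differential
    Expression and Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-wide summary figures that align genome-wide
    association study (GWAS) results, differential expression (DE) results,
    manually curated candidate genes, and arbitrary user-defined genomic
    feature tracks on a common per-chromosome coordinate axis. Significant
    markers and genes are selected by score and log2 fold-change thresholds
    (scores are -log10 p-values), laid out as stacked horizontal tracks inside
    one facet per chromosome, coloured by score, connected across tracks by
    vertical guide lines, and labelled with deterministic overlap-avoiding
    label placement. Includes a bridge for polyploid GWAS output organised by
    trait and genetic model with per-track significance thresholds, a
    synthetic-data generator with planted significant regions, a declarative
    renderer-independent plot specification with JSON serialisation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cowplot,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
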