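Package: splicemapr
Title: Mapping Recessive Splice-Disrupting Variants from SNP Arrays, Resequencing and RNA-Seq Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative DNA plus RNA pipeline for identifying recessive
    splice-disrupting mutations in livestock pedigrees, as used to map lethal
    recessives segregating from elite sires. Provides autozygosity interval
    mapping from SNP-array genotypes (shared-homozygosity segment finding and a
    haplotype-sharing case/control scan), a case/control variant filter cascade
    with consequence classification and HGVS-style c. notation parsing,
    splice-junction extraction from gapped alignments with exon-skipping and
    cryptic-acceptor detection (PSI, isoform fractions, in-silico RT-PCR),
    polypyrimidine-tract acceptor-site scoring, candidate prioritization with
    predicted protein consequences, population genotyping statistics for a
    recessive lethal (carrier frequency, exact deficit-of-homozygotes test),
    and a seeded synthetic-study generator emulating a half-sib population
    segregating one recessive lethal founder haplotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    broom,
    optparse
Config/testthat/edition: 3
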