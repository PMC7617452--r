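Package: sedna
Title: Population Genomics of Mixed-Species Sedimentary Ancient DNA
Version: 0.1.0
Authors@R: person("sedna", "maintainers", email = "sedna@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for extracting
    population-genetic and phylogenetic signal from mixed-species ancient
    environmental DNA. Provides a seeded synthetic-data generator (diverged
    reference pairs, coalescent genotype panels, deaminated read sets), a
    brute-force-verifiable end-to-end read mapper with competitive
    two-reference partitioning, terminal-deamination damage profiling and
    authentication, branch-assigned transversion SNP placement on a rooted
    mitochondrial phylogeny, pseudo-haploid population genetics (rescaled
    Hamming distances, neighbor joining, PCA projection of sparse samples,
    f4 statistics with block jackknife), and a heterozygosity-conditioned
    derived-allele-fraction divergence statistic calibrated against its
    coalescent one-third null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    withr,
    Biostrings,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
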