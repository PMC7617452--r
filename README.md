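# sedna

Population genomics of mixed-species **sed**imentary **a**ncient **DNA**, at
desk scale and fully testable.

DNA recovered from cave sediment can carry genome-wide information about
extinct populations — but as a mixture of species, in ultra-short damaged
fragments, at well under 0.1x coverage. `sedna` implements the analytical
core for working with such data as a reproducible R pipeline, exercised end
to end on synthetic inputs with known truth:

* **simdata** — seeded generators: diverged reference pairs, coalescent
  genotype panels (single-locus, genome-wide multi-locus, 2-3 populations
  with clean splits), deaminated fragment sets with per-read provenance,
  mixtures, VCF/FASTQ/FASTA/SAM serialisation.
* **readmap** — a brute-force-verifiable end-to-end (gapless) mapper,
  SAM text I/O (NM/MD handling), the `map_score >= 25` / `length >= 35`
  alignment gate, and the competitive partition of reads across two or k
  references (`presence` and `edit_arbitration` modes).
* **authenticate** — terminal substitution profiles (5' C->T, 3' G->A,
  exponential decay into the read) and an explicit ancient-like verdict:
  terminal rate >= 0.10 *and* terminal-vs-interior two-proportion z > 3.
* **mitoplace** — biallelic transversion SNPs from a mitogenome MSA,
  assignment of sites to branches of a rooted species tree (outgroup
  polarity), per-branch support/conflict tallies per read set, greedy
  best-path placement, plurality consensus (MSA) and the 66% / 3x pileup
  consensus rule.
* **popgen** — strict site filters (MQ > 20, AN > 150), pseudo-haploid
  calling (`random_read`, `single_read_only`), missingness-rescaled Hamming
  distances, Saitou-Nei neighbor joining, PCA with least-squares projection
  of sparse samples, and f4 statistics
  `f4(A,B;C,D) = mean[(pA - pB)(pC - pD)]` with a 500-SNP block jackknife.
* **divergence** — the heterozygosity-conditioned derived-allele fraction:
  at sites heterozygous in a high-coverage individual, the fraction of
  single-read calls in a second sample matching the alternate allele.
  Expectation 1/2 for the same individual, exactly 1/3 for a
  same-population sample (three-lineage coalescent argument), falling with
  population divergence — the package verifies all three behaviours by
  simulation and closed form.

See `vignettes/sedna-methods.Rmd` for the models, parameter choices,
numerical conventions and limitations.

## Worked example

A two-species mixture, competitively partitioned, authenticated, and the
same-population null of the divergence statistic:

```r
library(sedna)

sp      <- simulate_species_pair(length = 8000, divergence = 0.05, seed = 11)
reads_a <- simulate_ancient_reads(sp$ref_a, 300, fragment_model(), damage_model(),
                                  error_rate = 0.001, seed = 12, species = "A")
reads_b <- simulate_ancient_reads(sp$ref_b, 300, fragment_model(), damage_model(),
                                  error_rate = 0.001, seed = 13, species = "B")
mix   <- mix_read_sets(reads_a, reads_b, seed = 14)

aln_a <- filter_alignments(map_reads_end_to_end(mix$reads, c(A = sp$ref_a),
                           max_mismatch_rate = 0.07, damage_tolerant = TRUE))
aln_b <- filter_alignments(map_reads_end_to_end(mix$reads, c(B = sp$ref_b),
                           max_mismatch_rate = 0.07, damage_tolerant = TRUE))
part  <- competitive_partition(aln_a, aln_b, "edit_arbitration",
                               read_ids = mix$reads$id)
part
#> partition (edit_arbitration): unique_a=281 unique_b=279 shared=40 unmapped=0 of 600

truth <- setNames(mix$provenance$species, mix$provenance$read_id)
mean(truth[part$unique_a] == "A")
#> [1] 1

prof <- damage_profile(aln_a[aln_a$read_id %in% part$unique_a, ], sp$ref_a)
v    <- damage_verdict(prof)
#> ancient_like: TRUE (terminal 0.160 vs interior 0.0052, z = 9.4)

null <- null_expectation_same_pop(theta = 200, n_diploids = 10,
                                  n_replicates = 5, seed = 15)
#> same-population derived-allele fraction: 0.335 +- 0.017 (expected 1/3)
```

Reading the output: 560 of 600 reads are assigned to the correct species
(the 40 shared reads span no diagnostic site), assignment precision is 1.0
against the provenance truth, the retained read set shows the terminal
C->T excess of authentic ancient DNA (here 0.160 at offset 0 against an
interior rate of 0.005 — the terminal opportunity count is small, so the
rate is noisy, but the z-gate is unambiguous), and sampling one allele of a
second same-population individual at the high-coverage individual's
heterozygous sites recovers the 1/3 null.

An end-to-end divergence scan (`divergence_scan(c(0, 0.25, 0.5, 1.0),
seed = 77)`) maps damaged low-coverage reads through the full filter stack
and prints fractions `0.325, 0.259, 0.191, 0.096` — the deep-split value is
roughly half the same-population value, the qualitative contrast the
statistic is designed to expose.

## Command line

A thin CLI over the same functions is installed at `inst/cli/sedna`
(subcommands `simdata`, `readmap`, `authenticate`, `mitoplace`, `popgen`,
`divergence`; run without arguments for usage). Every stochastic command
requires `--seed`.

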