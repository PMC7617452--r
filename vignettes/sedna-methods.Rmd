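---
title: "Methods: population genomics of mixed-species sedimentary ancient DNA"
author: "sedna maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of mixed-species sedimentary ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA washed into cave sediment preserves genome-scale information about the
animals that deposited it, but it arrives as a worst case for population
genetics: ultra-short fragments (tens of bp), chemically damaged ends, very
low coverage (often well under 0.1x), and a mixture of species — including
close relatives whose reads cross-map. `sedna` implements, end to end and at
desk scale, the analytical core used to work with such data:

1. **Competitive mapping and read partitioning** — map each read against two
   (or k) candidate reference genomes and split the reads into
   unique-to-A, unique-to-B and shared sets.
2. **Damage authentication** — terminal C->T / G->A substitution profiles
   and an explicit ancient-like decision rule.
3. **Phylogenetic placement by branch-assigned SNPs** — assign biallelic
   transversion SNPs of a mitogenome alignment to branches of a rooted
   species tree, tally per-branch support/conflict for each read set, and
   walk a greedy best path from the root.
4. **Pseudo-haploid population genetics** — strict site filters, one-allele
   sample representations, missingness-rescaled Hamming distances, neighbor
   joining, PCA projection of sparse samples, f4 statistics with a block
   jackknife.
5. **A heterozygosity-conditioned divergence statistic** — at sites
   heterozygous in a high-coverage individual, the fraction of single-read
   calls in a second sample matching the alternate allele: 1/2 for the same
   individual, 1/3 for a same-population sample, lower with divergence.

Every stage is exercised on synthetic data with known truth; nothing needs a
download.

## The synthetic world

The generator states one world and the tests live in it.

* **Reference pairs** (`simulate_species_pair`): substitution-only
  divergence, each site differing with a fixed probability (default
  experiments use 0.05, the scale of two congeneric mammal species). No
  indels — this keeps end-to-end (gapless) alignment exact and lets a
  brute-force oracle verify the mapper, mirroring pipelines that restrict
  to end-to-end alignments.
* **Fragments** (`fragment_model`): shifted geometric, minimum 35 bp
  (25 bp in the mitochondrial mode), mean 55 bp — heavy on short fragments,
  as sediment libraries are. The empirical length distribution of real
  sediment libraries is not part of the contract, so the family and mean
  are configurable.
* **Damage** (`damage_model`): C->T at 5' offsets with terminal rate
  `delta5` decaying as `exp(-decay * offset)`, G->A at 3' offsets
  (double-stranded libraries; the single-stranded mode applies C->T at
  both ends). Defaults delta = 0.3, decay = 0.3: a well-preserved ancient
  sample; observed terminal rates > 0.13 are the plausible ancient range.
* **Genotype panels** (`simulate_coalescent_panel`): a standard neutral
  coalescent (exponential waiting times, uniform pair merges; a
  two-population version forbids cross-population coalescence more recently
  than the split), with infinite-sites mutations at rate theta/2 per
  lineage per unit of 2N generations, polarised 0 = ancestral/reference,
  1 = derived/alternate.

### Linkage: the one deliberate extension

One coalescent panel is **one genealogy** — a single non-recombining locus.
Three consumers of panels implicitly assume genome-wide *unlinked* markers:

* the f4 block jackknife (its SE is meaningless if all sites share one
  tree; unadmixed |Z| then routinely exceeds 3);
* PCA projection (axes of a single genealogy reflect that tree, not
  population structure);
* the derived-allele-fraction null (1/3 is a ratio of expectations, i.e. a
  *site-weighted* average; the per-genealogy ratio is biased low because
  site-rich genealogies — deep splits between the focal chromosomes — carry
  systematically lower fractions. We measured ~0.21-0.28 instead of 1/3 on
  single genealogies).

`simulate_multilocus_panel` therefore concatenates independent single-locus
panels, each one linkage block, exactly as a genome provides. The
single-locus generator keeps its specified contract; the genome-wide world
is used wherever the statistic presumes it. This is a modelling statement,
not a tuning knob: the statistics are *supposed* to be computed on
genome-wide SNP sets.

`simulate_three_pop_panel` adds a nested-splits (((1,2),3)) history via the
same structured-coalescent engine, used by the projection tests, which need
three populations.

## Mapping and partitioning

The mini-mapper scores every gapless placement of a read on both strands
(vectorised over positions; verified against a position-by-position
brute-force oracle on references up to 20 kb). A placement is reported when
its mismatch score is within `ceiling(max_mismatch_rate * length)`.
`map_score` is a pass/fail surrogate for mapping quality: 37 when the best
placement is unique within budget, 0 on ties — the downstream gate
(`filter_alignments`, `map_score >= 25` and length >= 35) only needs the
pass/fail distinction, because true MAPQ models are mapper-specific.
Deterministic tie retention: lowest start, then forward strand.

`damage_tolerant = TRUE` half-weights the two deamination mismatch classes
(reference C read T, reference G read A, in forward orientation — between
them these cover terminal damage on either strand of a double-stranded
library), so authentic ancient reads are not pushed over the budget by
their damage.

The competitive partition has two modes because "mapped uniquely" is
genuinely ambiguous: `presence` (unique = accepted by exactly one
reference) and `edit_arbitration` (a doubly-mapped read goes to the
reference with strictly smaller edit distance; ties stay shared). Presence
mode is only informative at a stringent mismatch budget — with a permissive
budget every read of either species is accepted by both references and the
unique sets are empty; the acceptance experiment therefore maps at
`max_mismatch_rate = 0.07` (the analogue of strict ancient-DNA mapper
settings), where both modes reach precision 1.0 on a 5%-diverged pair.
Partition exhaustiveness and disjointness are fuzz-tested invariants.

## Damage profiling and the verdict

`damage_profile` tallies all 12 substitution classes at the first K = 25
positions from each read end (read-relative orientation; K = 25 is common
damage-profiling practice), with exact opportunity counts, so
`frequency x opportunities = count` holds as integers. The decision rule in
`damage_verdict` is deliberately explicit and conservative, because the
source analyses report observed rates but no cutoff: ancient-like requires
*both* a terminal 5' C->T rate of at least 0.10 (below the > 0.13 observed
in authentic material, to retain moderately damaged samples) *and* a
two-proportion z > 3 of terminal versus interior (offsets 10-20) rates.
Zero-damage simulations never trip the rule; simulations across
delta in [0.1, 0.4], decay in [0.1, 0.5] recover the terminal rate within
3 binomial sigma at >= 1000 opportunities.

## Placement on the mitochondrial tree

MSA columns are the universal coordinate system, and the plurality
consensus of the MSA is the mapping target — mapping all read sets to one
neutral consensus avoids choosing either species' reference and keeps
coordinates identical to the alignment. With substitution-only MSAs the
consensus coordinates equal MSA columns exactly.

Site extraction drops columns that are non-ACGT in the designated reference
row or not biallelic; the transversion-only switch removes the A/G and C/T
classes that deamination can mimic. A site is assigned to the branch whose
clade equals one allele's carrier set; the derived allele is the one on the
side away from the designated outgroup (outgroup rooting, not midpoint; a
giant-panda-like outgroup is the natural root in the motivating system).
Sites with no clade match are reported as homoplasic, or as missing-data
when excluded rows (or an unscored outgroup at a root split) prevent a
clean match.

Support tallies are **per site, not per read**: the plurality base across
covering reads decides support (derived) or conflict (ancestral), ties
skip the site, and each site contributes at most once per read set — deep
read stacks cannot dominate single-copy signal. `best_path` descends
greedily from the root accepting the child branch with maximal additive
net score (support − conflict) only when support >= 1 and net > 0,
stopping at ties, leaves, or unacceptable children. The additive rule and
plurality resolution are documented choices; the published tool's exact
internal scoring is not stated, so the rule here is operational and
simulation-tested: on infinite-sites toys the true source tip is recovered
with zero conflicts on the accepted path, and a single injected conflicting
SNP against >= 2 net support does not move any path.

Consensus from read pileups uses the 66% / 3x rule: a base is emitted only
with depth >= 3 and plurality fraction >= 0.66, else N; the rule is monotone
(raising thresholds never un-Ns a site) and its truth table is enumerated
in the tests.

## Pseudo-haploid population genetics

* **Site filter**: MQ > 20 and AN > 150, both strict, AN recomputed from
  the genotypes. Strict AN > 150 implies >= 76 fully-called diploids of an
  83-sample panel; the panel's descriptive gloss ("at least 75") differs by
  one — the printed strict filter is implemented.
* **Pseudo-haploid calls**: `random_read` (one uniformly chosen read per
  site) or `single_read_only` (call only where exactly one read overlaps —
  the guard against amplification bias; mandatory inside the divergence
  statistic). Calls not matching ref or alt are missing. Randomness is
  seeded per sample.
* **Hamming distances**: raw L1 distance on dosages over jointly observed
  sites, rescaled by (total sites / pair-observed sites). The rescale is
  unbiased under missing-completely-at-random thinning (simulation-tested);
  the external tool's exact flat-missing formula is not printed anywhere,
  so this proportional rescale is the documented interpretation.
  Pseudo-haploid samples are doubled to {0,2}; the resulting self-distance
  inflation at heterozygous sites is reported by a test, not hidden.
* **Neighbor joining**: textbook Saitou-Nei with the Q criterion,
  deterministic tie-break, negative branch lengths clamped to zero with a
  warning; equals `ape::nj` on 50 random additive matrices and recovers
  additive trees exactly.
* **PCA projection**: sites centred at 2p and scaled by sqrt(p(1-p)) from
  the modern panel; modern scores from the SVD; sparse ancient samples
  enter by least squares of their standardized non-missing entries on the
  loadings. A per-component shrinkage multiplier exists but defaults off —
  the published tool's shrink procedure is unspecified, and plain least
  squares is the reproducible core.
* **f4**: mean of (pA − pB)(pC − pD) over sites where all four populations
  have frequencies; SE by delete-one-block jackknife over consecutive
  blocks of 500 usable SNPs (coordinate order; the last block may be
  short, handled by the weighted jackknife, which reduces exactly to the
  standard delete-one form for equal blocks). Admixture-graph search is
  out of scope; the f4 machinery tests graph-implied constraints directly.

## The divergence statistic

`call_het_sites` is a minimal maximum-likelihood diploid caller over
{RR, RA, AA} with symmetric base error eps = 0.01 and a Phred-scaled
likelihood margin as call quality; the retained sites satisfy call
quality > 20, MQ > 25, depth in [15, 40] (inclusive), heterozygous,
transversion, biallelic. A fixed-eps caller stands in for an external
caller because only the downstream filters are contractual and the caller
must be oracle-checkable.

`derived_allele_fraction` then counts, over those sites, single-read calls
in a second sample that equal the alternate allele ("derived" is
operationalised as "alternate relative to the reference orientation", the
two terms being used interchangeably in this analysis style). Third
alleles are set to missing. Exact binomial CIs are attached.

The same-population expectation is exactly 1/3 — with three lineages,
conditional on the first two differing, the third carries the derived
allele with probability 1/3; the package's tests verify this against a
closed-form three-lineage enumeration and recover it by simulation (within
3 MC SE for theta in {5, 20, 80}, and through the full
damage + mapping + filtering stack at split time 0). `divergence_scan`
shows the fraction falling monotonically with split time — the scan uses
paired per-replicate seeds across split times (common random numbers), a
variance-reduction choice that makes the ordering visible at 10 replicates
without touching the estimates themselves. A representative run prints
fractions ~0.32 / 0.26 / 0.19 / 0.10 at splits 0 / 0.25 / 0.5 / 1.0: the
deep-split value sits at roughly half the shallow ones, the qualitative
contrast (a diverged population near 17% against same-population values
in the low 30s) that motivates the statistic.

## What a green test does and does not establish

The generator emulates substitution divergence, terminal deamination,
uniform error, and clean population splits. It does **not** emulate indels,
reference-bias from divergent mapping beyond substitutions, repetitive
reference content (reads are effectively unique at these reference sizes),
contamination by further species, or base-quality variation. Green tests
establish that the algorithms are correct in this stated world and that
the statistics behave per their closed-form expectations — not that any
particular real sample would yield the published numbers, which depend on
the real sequencing data.

## Numerical choices and degenerate inputs

Ties are resolved deterministically everywhere (mapper: lowest start then
forward strand; consensus: A < C < G < T; NJ: first minimal Q pair in
row-major order; plurality tallies: ties skip the site). Undefined
quantities carry explicit status instead of silent zeros: verdicts with no
interior opportunities, distance pairs with zero joint observations,
derived fractions with no observed site. Every stochastic entry point takes
a single integer seed and is bit-reproducible under it.
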