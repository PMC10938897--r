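---
title: "Models and methods: simulating and analysing allopolyploid genome evolution"
author: "polyevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing allopolyploid genome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyevolve)
```

# Scope

`polyevolve` implements the comparative-genomics chain used to characterise a
recently formed allotetraploid plant genome: detecting whole-genome
duplications (WGDs) from the synonymous-divergence (Ks) distribution of
collinear paralogs, dating them against an anchored calibration, phasing
chromosomes into subgenomes with differential k-mers, quantifying biased
homoeolog loss (fractionation), reconstructing ancestral karyotypes by
synteny painting, and summarising population-level diversity. Because the
raw genome assemblies such analyses start from are far beyond desk scale,
the package pairs every analysis stage with a genome-evolution simulator
that produces gene-ordered genomes *with a truth ledger*, so each stage can
be tested as a parameter-recovery problem.

The motivating system is a tetraploid aquatic weed with 2n = 4x = 32: two
subgenomes of eight chromosomes each, shaped by three nested WGD epochs (an
ancient duplication shared with related monocot lineages that serves as the
dating anchor at 129–146 Mya, a lineage-specific duplication, and the recent
tetraploidizing merge), strong post-WGD contraction of disease-resistance
gene families, and a near-clonal global population.

# The simulator

## Substrate

A genome is an ordered list of chromosomes carrying ordered, stranded genes
(`rank` is the 0-based position in gene order; all interval conventions are
0-based half-open). Genes carry a family label and an in-frame coding
sequence drawn uniformly over the 61 sense codons. Gene order, not base-pair
position, is the coordinate system for synteny — mirroring collinearity
tools that operate on gene ranks.

## Events

Histories are ordered lists of events, oldest first, with ages in Mya:

* **WGD(k)** copies every chromosome and gene `k`-fold and records each
  copy's lineage token in the ledger.
* **Fission / fusion / inversion** edit the karyotype; fusion appends
  end-to-start with an optional orientation flip; ranks are renumbered.
* **Loss epochs** delete each gene by an independent Bernoulli draw with a
  per-family rate multiplier. The last surviving copy of an ancestral locus
  is protected unless extinction is explicitly allowed, which keeps
  homoeolog quartets well-defined for retention analyses.
* **TE bursts** insert copies of a family consensus mutated to a target
  percent divergence (per-base Bernoulli mismatches) — the PercDiv statistic
  measured downstream is therefore exactly the generating parameter.
* **Sequence epochs** set the synonymous substitution rate per site per My.

## The synonymous clock and its calibration

Sequence divergence is synonymous-only: a continuous-time walk on the
synonymous single-step codon graph (each neighbour at rate 1/3, i.e. unit
rate per NG86 synonymous site). This keeps proteins fixed and makes Ks the
only divergence axis, matching how the dating analyses use the data.

Applied naively, the NG86 + Jukes–Cantor estimator is biased upward on this
process at higher divergence: two-fold degenerate sites saturate toward an
observed difference of 1/2 on a site measure of 1/3, which exceeds the 3/4
saturation the correction assumes. Instead of accepting that bias, the
simulator computes the exact expected NG86 estimate as a function of walk
time from the walk's generator (a symmetric 61 x 61 rate matrix,
eigendecomposed once) and spends the event time whose *expected estimate*
equals the nominal Ks. All ledger truths — the `expected_pair_ks` of every
duplication event, and `true_ks()` for any gene pair — are therefore on the
scale that `ng86()` reports, and recovery tests compare like with like.
Verified accuracy is within ~4% up to Ks 1.5 at gene lengths of 100 codons
and above.

## Default study conditions

`simulate_allotetraploid()` encodes the study architecture: an 8-chromosome
proto ancestor; the ancient WGD at Ks 1.5 followed by 1 fission and 13
fusions down to the n = 4 intermediate; the lineage-specific WGD at Ks 0.7
creating the within-subgenome ancestral groups (A1/A2, B1/B2); hub
translocations plus an inversion so each group forms one connected synteny
bundle (without such rearrangements the group partition is provably
unidentifiable — any per-pair copy swap gives the same synteny cut);
the progenitor split at homoeolog Ks 0.1; subgenome-specific TE bursts at
5% (subA) and 19% (subB) divergence; and a post-merge fractionation epoch
(default rate 0.2 per copy) with family multipliers (4x and 2x on two
families standing in for fast-fractionating disease-resistance families).
The clock is 0.0025 substitutions per synonymous site per My, so the three
epochs sit at 300, 140 and 20 Mya in simulation time; only Ks ratios matter
downstream. The progenitor-split age and the merge age are deliberately
separate knobs (`ks_split` sets the divergence; the merge itself is
instantaneous), since the study system constrains their combination, not
each one.

The population module emulates resequenced lines of a clonal invader: 10
samples in 4 distinct genotypes (one dominant clone), genotypes coded as
homozygous dosages, mutation probability per site calibrated so that the
expected nucleotide diversity equals the target `theta` (default
1.44 x 10^-3) given the clonal structure, and a plastome pair differing by a
single 1-bp indel.

What the simulator does *not* model: recombination, selection, incomplete
lineage sorting, indels inside coding sequence, tandem duplication, and TE
nesting. Passing recovery tests on these genomes therefore demonstrates the
correctness of the analysis logic, not robustness to every artefact of real
assemblies (fragmentation, mis-assembly, annotation error).

# Analysis stages

## Homology and synteny chaining

Candidate homolog pairs come from shared family labels; in `sequence` mode
they are scored by CDS 6-mer Jaccard similarity, which cleanly separates
same-locus copies from remote family co-members. Chaining is sparse dynamic
programming per chromosome pair: chains must be strictly monotone on both
chromosomes (decreasing on the second for inverted blocks) with at most
`max_gap = 50` intervening gene ranks between consecutive anchors on either
chromosome — the gap is counted in genes, not base pairs. Chain score is
anchor scores minus `gap_penalty * gap / 10` (gap = the larger of the two
rank gaps; penalty 0.5 by default); only `max_gap` is externally fixed, so
the score shape is a package choice, exposed as arguments. Both orientations
compete per chromosome pair; the best chain is extracted, its anchors
removed, and the search repeated down to `min_block = 5` anchors (the block
floor is our choice, exposed as a flag). Ties break toward the chain with
the smaller start rank. On every instance small enough to enumerate, the DP
equals exhaustive search over monotone chains (tested).

Note one ascertainment caveat: a similarity floor (`min_score`) biases
anchors at high-divergence epochs toward the less-diverged pairs, which
deflates the oldest Ks peak slightly. The default floor (0.12) is set low
enough to retain anchors from an epoch at Ks 1.5 while excluding the
random-pair similarity floor (~0.04).

## Ka/Ks and peak fitting

`ng86()` implements Nei–Gojobori (1986) counting: per-codon synonymous site
fractions averaged over both sequences, observed differences averaged over
all minimal substitution pathways excluding those through stop codons
(falling back to all pathways when every one is blocked), and Jukes–Cantor
correction. Saturated pairs are flagged and excluded from distributions
rather than clamped, to avoid artificial mass at high Ks.

`fit_ks_peaks()` fits a Gaussian mixture to log Ks with the component count
chosen by BIC (via `mclust`); values above `ks_max = 3` are discarded first.
Peak locations are reported as the component centre `exp(mu)` (the
back-transformed mean of log Ks), with the lognormal mode `exp(mu - sigma^2)`
alongside; the centre is the quantity used for epoch recovery and dating,
the mode is what a density plot's peak would show. With well-separated
epochs the fit occasionally adds a tiny outlier component; the dominant
components carry the epochs.

`anchored_dating()` is a linear molecular clock: each peak is dated as
`(mu_i / mu_anchor) * [T_min, T_max]`, propagating only the anchor's
interval (129–146 Mya for the shared ancient WGD in the study system). The
transform is scale-free in Ks. Peak-location uncertainty is not propagated
by default. `relative_rate()` provides the outgroup contrast (median Ks
ratio with a paired bootstrap interval) used to diagnose lineage rate
variation.

## Subgenome phasing and TE landscapes

`kmer_profile()` counts canonical (strand-collapsed) k-mers per chromosome;
k = 13 by default — smaller than the k = 15 of assembly-scale phasers
because simulated chromosomes are short; both are exposed. Phasing
iterates: hierarchical clustering of the frequency profiles seeds a
partition; class-specific k-mers (>= 2-fold enrichment) are recomputed and
every chromosome reassigned to the class whose specific k-mers it carries
most of, until a fixed point. The consistency score is the mean share of
specific-k-mer signal behind each assignment; chromosomes with no
subgenome-specific content converge to the uninformative value 1/n and are
thereby flagged unphaseable.

TE landscapes bin each copy's percent divergence from its family consensus
(1% bins over [0, 50]). In tests the consensus is the simulator's true
sequence; for real input a majority-rule consensus per family is computed.
The "bubble" — the divergence interval separating the two subgenomes' TE
populations, which corresponds to the period between progenitor divergence
and merging — is computed from the per-subgenome cumulative distributions:
divergence values d such that at least `threshold` (default 0.75; the
original description is qualitative) of the younger subgenome's copies lie
below d and at least `threshold` of the older's lie above. Identical
landscapes give an empty interval; threshold 0 degenerates to the full
range.

## Retention and fractionation statistics

Chromosomes are first assigned to ancestral groups within each subgenome by
exact maximum-cut over the anchor weights (chromosome counts are small
enough to enumerate all bipartitions); WGD-derived blocks connect a
chromosome to its duplicate across the cut. Ambiguity — several structurally
distinct optimal cuts, or no within-subgenome synteny — is flagged rather
than silently resolved. Ancestral loci are connected components of the
anchor graph over all genes (orphans are single-gene loci), with blocks
Ks-screened to the events under study so that older duplications do not
merge homoeolog-level loci. "Retention" is syntenic: a locus is present in
a group only if a copy lies in that group's chromosomes inside a qualifying
block, matching the synteny-retention-ratio definition; ratios are reported
per locus (the denominator choice is exposed, locus mode default). The
quartet class requires all four groups, pair classes both groups of one
event, and the homoeolog class at least one copy per subgenome.

Depletion and enrichment use the exact hypergeometric test, two-sided by
the minimum-likelihood rule (`stats::fisher.test`), with raw p-values by
default and Benjamini–Hochberg available via `p.adjust` on the caller's
side. Family-size comparison reports per-family fold changes (query over
reference), the modal fold (exactly 2 for a clean WGD against its diploid
progenitor), and a per-family 2x2 Fisher test of the family's share of the
two gene complements.

## Karyotype painting and bookkeeping

Chromosome counts obey `C = k * n + fissions - fusions`; `event_bookkeeping`
validates declared trajectories (for the study system: 8 proto-chromosomes,
the ancient WGD, 1 fission and 13 fusions give the n = 4 intermediate) and
`infer_events` inverts a painting (`fissions = S - k n`, `fusions = S - C`).
When a fission's fragments later re-fuse, the inverted counts are minimal
rather than exact, and are reported as such. The declared second transition
of the study system (3 fissions and 13 fusions from n = 4 to 8 chromosomes
under a single doubling: 4*2 + 3 - 13 = -2) does not balance and is treated
as a validation-failure example rather than guessed at.

Painting uses cross-genome blocks among at least three genomes: block
boundaries cut each chromosome into atomic intervals; intervals linked by
any qualifying block are merged union-find style; the connected components
are the proto-chromosomes; same-label neighbours merge back into segments
that tile each chromosome, with uncovered intervals absorbed into their
labelled neighbour so coverage gaps do not inflate segment counts. Segment
orientation is not currently derived from block orientation (a known
limitation). This is parsimony-flavoured bookkeeping, not a rearrangement
(DCJ) solver — by design, matching the additive fission/fusion narrative the
analysis supports.

## Population diversity

Sites are filtered exactly as the study pipeline specifies: drop when minor
allele frequency < 0.01 (computed over non-missing allele calls — the MAF
denominator is our choice) or missing rate > 30%. Nucleotide diversity is
the mean pairwise expected allele difference per site over all unordered
sample pairs (`(g_i(2-g_j)+g_j(2-g_i))/4` for dosages), pairwise-complete
for missing data with each pair rescaled to the full polymorphic-site
count, and divided by the total surveyed sites including monomorphic ones.
Trees are canonical Q-criterion neighbor joining (`ape::nj`) on p-distances
with negative branches clamped to zero and noted; PCA is the
eigendecomposition of the genotype covariance centered at `2p` and scaled
by `sqrt(2p(1-p))`, mean-imputed, with each component's sign fixed so its
largest-magnitude coordinate is positive.

`compare_plastomes()` handles organelle-scale near-identical pairs without
quadratic alignment: k-mers unique in both sequences (k = 21) are matched,
chained by longest increasing subsequence, thinned to a ~200 bp stride, and
the inter-anchor stretches aligned globally; a stretch longer than
`max_segment` (20 kb) means anchoring failed and is an explicit error, never
a silent partial answer. Mismatch columns are SNPs; each maximal gap run is
one indel event with its length recorded.

# Numerical and reproducibility choices

Every stochastic entry point takes a seed; `child_seed()` derives bounded
per-stage seeds from one top-level seed so that pipeline stages have
independent reproducible streams, and `run_demo()` writes a manifest of MD5
checksums that is identical across runs with the same seed. Mixture fitting
is deterministic given the data. Chaining and grouping ties break by fixed
lexicographic rules. Degenerate inputs (empty anchor sets, empty landscapes,
all-missing sites, unphaseable profiles) return typed empty results or
flagged outputs rather than errors, except where silence would be misleading
(plastome anchoring failure, inconsistent karyotype histories).

Problem sizes in the tests and in `scripts/acceptance.R` are chosen so the
statistical checks have sensible power at desk scale: Ks-epoch recovery uses
~350 pairs per epoch at 300 codons (keeping the mixture-fit standard error
well inside the 10% recovery band); retention ranking uses 20 replicates of
a 4-proto-chromosome tetraploid with ~40 loci per family; phasing accuracy
uses 20 seeded tetraploids. The demo pipeline at default sizes runs in well
under a minute on one CPU.

# Known limitations

* The NG86-scale calibration assumes a uniform sense-codon composition at
  the start of each branch; after long walks the composition drifts toward
  the stationary distribution of the synonymous graph, so deeply nested
  epochs carry a residual bias of a few percent.
* High-divergence anchors are ascertained through the similarity floor,
  deflating the oldest peak slightly (see above).
* Painting reports minimal fission/fusion counts when histories re-fuse
  fission fragments, and does not annotate segment orientation.
* The population model is calibrated for expected diversity, not for a
  full coalescent; linkage and recombination are absent.
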