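---
title: "Methods: miRNA discovery and comparative analysis with mirnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and comparative analysis with mirnaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaforge)
```

## Overview

`mirnaforge` reimplements, as a tested and reusable R pipeline, the
standard small-RNA workflow for discovering novel microRNA loci in an
insect genome and characterising the resulting repertoire: read
cleaning, hairpin-based locus calling, arm-usage and arm-switch
analysis, 5'-isomiR fidelity, sex-biased differential expression,
seed/energy consensus target prediction, cross-genome homolog
validation, and genomic cluster analysis. A synthetic-data generator
produces genomes with planted pre-miRNA hairpins and read libraries
with known ground truth, so every stage can be validated end to end
without any external sequencing data.

All intervals inside the package are 0-based and half-open on the
forward strand; conversion to GFF3 (1-based, closed) happens only at
the file boundary, and a round-trip test pins this convention.

## Secondary-structure model

Precursor folding uses a Nussinov-style dynamic program that maximises
a weighted count of nested base pairs (G:C = 3, A:U = 2, G:U wobble =
1) with a minimum hairpin loop of 3 nt. Full thermodynamic folding is
deliberately out of scope: the analyses only need hairpin presence and
the geometry of the mature/star duplex, and an exact pair-maximisation
optimum can be verified against an exhaustive enumeration oracle on
short sequences, which the test suite does for 200 random sequences up
to 20 nt. A `fold_engine` hook on `fold()` accepts an external
thermodynamic folder returning the same pairing representation for
cross-checks.

Pair maximisation admits many co-optimal structures. The traceback is
deterministic and pairs the leftmost base with its most distal
admissible partner first, which reconstructs designed hairpin stems
outside-in whenever a planted duplex is among the optima. Scores are
tie-break independent.

Two duplex-geometry statistics drive validation, with the package's
own operational definitions (the quantities are named but not defined
in the primary literature):

* **space** — the number of nucleotides strictly between the
  loop-proximal ends of the mature and star intervals (for a clean
  hairpin this is the terminal loop length);
* **max bulge** — the longest contiguous run of positions inside the
  mature/star duplex, on either strand, not paired to the opposite
  arm.

Accepted duplexes require space ≤ 35 nt and bulge ≤ 5 nt; both limits
are exposed as parameters.

## Locus discovery

Clean tags are mapped to the genome with full-length exact matching
(zero mismatches) on both strands; tags hitting more than `max_hits`
(default 5) genomic positions are flagged repetitive and excluded,
which operationalises retaining non-repetitive loci. Identical
alignments pile into *stacks*; stacks whose 5' ends lie within ±2 nt
form a *5' family* (the same window used for isomiR cataloguing).

Every stack holding at least `min_anchor_reads` (2) identical reads
seeds a candidate. Around the seed two excision windows are tried — 15
nt on one side and 70 nt on the other, in both orientations — because
the star side is unknown a priori. Star identification is
evidence-first: each read-supported stack in the window that does not
overlap the mature is tested as the star by folding only the trimmed
putative precursor (both arms plus the intervening sequence, no
flanking), and the candidate with the highest mature-into-star paired
fraction wins. Folding the trimmed precursor rather than the whole
window matters: pair maximisation over a window with ~90 nt of
flanking sequence freely pairs the flanks and can bury a genuine
duplex in spurious structure. When no read-supported star exists the
expected star interval is inferred from the window fold and geometry
re-measured on the trimmed precursor, so that loci failing only on
star evidence are still reported with meaningful geometry.

Candidates are then classified in evidence-first order:
`no_hairpin` (mature pairs < 60% into any candidate star),
`low_mature` (mature family < 10 reads summed across libraries),
`no_star` (no star-family read), `space_exceeded`, `bulge_exceeded`,
otherwise accepted. The 10-read mature threshold is interpreted as
summed across libraries (the source description is ambiguous between
per-library and pooled counts; pooled is the weaker and more common
reading).

The mature arm is the seeded (higher-count) arm, with ties broken
toward 5p; this affects arm-usage labels only.

## Synthetic data

The generator plants hairpins built by `build_hairpin()`: mature arm,
terminal loop (default 10 nt), star arm as the exact reverse
complement, and a 2-nt star 3' overhang (the canonical Drosha/Dicer
signature; configurable 0-3 nt since overhang geometry is a modelling
choice). Overhang and bulge-insertion bases are chosen to be
unpairable against the relevant arm so planted geometry survives pair
maximisation.

Default study conditions emulate a six-library male/female adult
small-RNA experiment:

* genome 100 kb with 30 loci, two clustered pairs at gaps of 73 and
  920 nt (the distances observed for a planthopper-specific cluster in
  three genomes);
* mature lengths 18-30 nt peaked at 22 nt, 70% U at the 5' end;
* dominant-arm read fraction (`arm_bias`) 0.8; `star_fraction`, when
  given, is the equivalent star/mature parametrisation
  (`arm_bias = 1/(1+star_fraction)`);
* 5' jitter over offsets −2..+2 with modal mass 0.8 for mature reads
  and a broader spectrum (modal mass 0.5) for star reads, emulating
  the lower 5' precision of star species;
* six libraries (3 male, 3 female) of 10^5 reads; 10 sex-biased loci
  with log2 fold changes drawn N(0, 2) (or a fixed magnitude when
  requested);
* per-locus mean abundance log-normal with meanlog = log(100 CPM),
  sdlog = 1 — the generator's one invented distribution, chosen as a
  realistic abundance spread; nothing in the source constrains it;
* 10% background decoy reads from non-locus genome positions, so the
  preprocessing and discovery filters have real work;
* two sister genomes derived by per-base substitution (default 2%),
  preserving coordinates, as homology truth.

Qualities are constant; no sequencing-error model by default (with
zero-mismatch mapping, errors are equivalent to decoys), though a
substitution rate is available. Reproducibility is exact: the
simulation is a deterministic function of the configuration including
its seed.

What the generator does *not* emulate — 3' isomiRs and non-templated
additions, ligation and GC biases, true transposon repeats, indel
divergence between genomes — bounds what passing tests show about real
libraries: they validate the algorithmic contracts, not robustness to
every artefact of real sequencing.

## Profiles: arm usage and 5' isomiRs

Arm dominance uses a ratio threshold r = 2 (the dominant arm needs
twice the reads of the other); the source calls dominance
qualitatively, so r is exposed and results for r ∈ {1.5, 2, 4} can be
compared by rerunning `arm_usage()`. An arm switch between two
datasets requires both profiles dominant on opposite arms; codominance
gives `indeterminate`. 5'-isomiR profiles count reads by 5' offset
within ±2 nt of the annotated end; *fidelity* is the modal share.
The mature-vs-star fidelity contrast uses an exact two-sided sign test
over non-tied loci.

## Differential expression

The negative-binomial exact test of the original tool chain is
replaced by a depth-normalised exact binomial test on
condition-pooled counts: for each miRNA, the female-pool count is
tested against the proportion implied by the condition depths
(two-sided `binom.test`), with BH-adjusted FDR reported alongside and
bias called at raw p < 0.05 (the quoted significance rule; whether
that p was raw or adjusted is ambiguous in the source — raw is
implemented as the call threshold, FDR is reported). Under the
generator's Poisson model the pooled conditional distribution is
exactly binomial, so the test is calibrated by construction; the
suite verifies type-I error in [0.03, 0.07] at n = 500 and power ≥
0.9 at |log2FC| = 2 with correct direction. A quasi-binomial variant
is not needed for the generator's noise model and real overdispersed
data would require one; this is a documented limitation.

## Target prediction

Two criteria stand in for the original three-program consensus (the
alignment-scoring program is not reimplemented; with two remaining
criteria the "at least two programs" rule becomes seed AND energy):

* **seed**: exact Watson-Crick reverse complement of miRNA positions
  2-8 (7-mer default, 8-mer option), no mismatches, no G:U;
* **energy**: nearest-neighbour stack energies (Xia/Turner 37 °C
  Watson-Crick table, +4.09 initiation, +0.45 per terminal A:U)
  summed over the best ungapped duplex core across all antiparallel
  offsets, threshold ΔG ≤ −20 kcal/mol. G:U is treated as unpaired,
  consistent with the seed rule; absolute energies therefore differ
  from full hybridisation models and the cutoff is configurable.

Energy is monotone under extending the complementary core (each added
stack is at least 0.93 kcal/mol stabilising, exceeding the worst
terminal-A:U penalty change of 0.45), which the suite asserts.

## Homology and clusters

Homolog search seeds on 7-mer words (both strands), extends each
seeded diagonal to a full ungapped placement of the query, and keeps
placements covering ≥ 80% of the query at ≥ 85% identity — a
deliberate stand-in for a BLAST E-value cutoff, which depends on
database size and scoring choices that are not pinned down. Each
location is extended ±90 nt, folded, and the implied duplex validated
with the same space/bulge limits as discovery, structure-only (no
expression requirement for the star arm, matching the method's
description). Verdicts: `homolog`, `no_hairpin` (the match pairs
almost nowhere), `geometry_fail`.

Pair maximisation with wobble pairs finds spurious "duplexes" for a
22-mer against ~90 nt of random sequence surprisingly often, so a
validated homolog requires two additional screens in place of the
thermodynamic stability a full folder would provide:

* **duplex score density ≥ 2.0** — mean pair weight per query
  position; 2.0 is the density of a perfect all-A:U duplex, so any
  fully Watson-Crick duplex meets it by construction and moderate
  substitution divergence keeps typical (mixed-composition) duplexes
  above it, while chance matchings lean on wobble pairs and fall
  below;
* **register consistency ≥ 0.5** — the fraction of query positions
  paired on the modal duplex diagonal. Substitution-diverged homologs
  keep a single register, and a bulge of up to 5 nt splits it at
  worst in half (hence 0.5); chance duplexes assembled by pair
  maximisation hop between registers.

A corner case follows from the density definition: an all-A:U query
whose duplex loses any pair to the window fold dips below 2.0 and is
rejected; compositionally extreme queries are the price of a
wobble-penalising screen.

Clusters are single-linkage chains of loci with inter-precursor gaps
≤ 10,000 nt (a common convention; the observed clusters sit far below
it, and the threshold is a parameter). Singletons are not clusters.
Orthologous clusters across genomes are matched by shared member
seeds (positions 2-8), not synteny. `cluster_distance_ratio()`
reports one genome's intra-cluster gap against the mean of the
others, raw and rounded: for the observed gaps of 73, 67 and 920 nt
it returns 920/70 = 13.1, i.e. a 13-fold expansion.

## Numerical and design choices

* Exact matching, substring containment and FASTA/FASTQ parsing are
  delegated to Biostrings; GFF3 to rtracklayer/GenomicRanges; BH
  adjustment to `stats::p.adjust`; Fisher tests to
  `stats::fisher.test`. The scientific logic documented above is
  implemented in the package.
* Known-ncRNA annotation precedence is known_miRNA > rRNA > tRNA >
  snRNA > snoRNA (a repo decision; the source states none). Matching
  is exact substring containment on either strand.
* Adapter trimming requires a terminal overlap of ≥ 4 nt; adapterless
  reads are retained.
* Degenerate inputs: empty tag sets, empty genomes and zero-read loci
  return empty results or typed errors naming the offending input;
  probability vectors must sum to 1; an optional fold-score cutoff
  for discovery exists but is off by default (the original tool's
  undocumented defaults cannot be mirrored).
* Problem sizes in the test suite (100 kb genomes, 30-50 loci, 20 kb
  mapping-oracle genomes, 500-miRNA DE simulations) are the package's
  validation scale, chosen so the full suite exercises every stage at
  depth while remaining quick to run.

## Known limitations

* Pair maximisation is not thermodynamics; structures with equal pair
  weight but very different stability are not distinguished beyond
  the duplex-density screen.
* The DE test assumes Poisson-level library noise after pooling;
  biological replicates with overdispersion need a different test.
* Homolog search is substitution-only (ungapped); indel divergence
  between genomes degrades recall faster than the simulated
  substitution series suggests.
* The generator's 5'-jitter model is symmetric and truncated at ±2
  nt; real Dicer heterogeneity can be wider and asymmetric.
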