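---
title: "dupscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dupscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dupscan is a phylogenomic toolkit for finding duplicates of a set of query
genes across annotated genomes, deciding how each copy arose, whether it is
still functional, how many independent duplication events the copies
represent, and how the copies evolve relative to their parents. The package
targets the kind of study done on nuclear-transport genes in insects —
small gene families, compact genomes, a mix of RNA-mediated (retroposed) and
DNA-mediated duplicates, and substantial turnover through pseudogenization —
but nothing in the code is specific to that system.

This vignette documents the models and procedures, the tunable parameters
with their defaults and rationale, what the synthetic-genome generator does
and does not emulate, the numerical choices, and known limitations.

## The detection model

A duplicate copy of a query gene is found by translated homology search:
every contig is translated in all six reading frames, exact protein 4-mers
seed candidate regions (two seeds per diagonal band are required, the
standard two-hit heuristic), and candidates are extended by Smith-Waterman
local alignment under BLOSUM62 with affine gaps (open 11, extend 1, the
BLAST protein defaults; the identity cutoff is the only criterion the
original analyses state, so identity is the sole retention rule). Hits with
identity below 0.40 or fewer than 20 aligned residues are dropped. Because a
full optimal local alignment will happily bridge an in-frame intron with one
long gap — which would hide the intron — alignments are split at subject-side
insertions of 12 residues or more and at internal stretches whose cumulative
score falls below -20 (an X-dropoff-like rule emulating how BLAST reports
separate HSPs per exon).

Hits on one contig and strand are assembled into candidate loci by optimal
score-weighted colinear chaining: successive hits must advance in both query
and genome, genomic gaps are capped at `max_intron_bp` (20 kb — generous for
compact insect genes), and query overlaps of up to 10 residues are allowed
because exon-junction codons and alignment slop at diverged copies commonly
appear in both flanking hits. Chains are extracted best-first, so each hit
belongs to exactly one locus.

## Mechanism, status, identity

The mechanism rule is structural. A retrocopy, arising from a spliced mRNA,
aligns as one solid hit with no introns; a DNA-mediated copy retains the
parental exon/intron structure, so its exons appear as separate hits
punctuated by intron-scale gaps; a partially processed retrocopy retains a
proper subset of introns. Inter-hit genomic gaps of at least `min_intron_bp`
(40 bp, about the shortest credible spliceosomal intron) are mapped onto the
parent's intron positions expressed in protein coordinates. Each observed
junction is an interval (between the end of one hit and the start of the
next, which may overlap); a parental junction matches if it falls within
2 aa of that interval. Copies retaining zero parental introns are `retro`,
all of them `dna`, a proper subset `partial_retro`. Loci covering less than
half the query are `fragment`s: they are reported but excluded from event
counting, since low search coverage (not truncation) is what makes a locus
uninterpretable. Copies of single-exon parents are `undetermined` — the
retro/DNA contrast needs parental introns to be visible.

A copy is a pseudogene when a premature stop codon removes at least 10
amino acids relative to the parent's stop, or when the reconstructed protein
is at least 10 residues short ("at least" makes exactly 10 a pseudogene).
To measure this on the genome rather than on local-alignment endpoints, the
copy's coding sequence is reconstructed by splicing out intron-scale gaps,
keeping sub-intron gaps (they are coding sequence — a premature stop sits in
one), and extending the terminal hits to the query's ends plus one codon.
An unreadable locus (reconstructed protein under 20% identity to the parent)
is a pseudogene with reason `unreadable`.

Protein identity to the parent is the global-alignment identity of the
reconstructed copy; age classes use strict thresholds (young > 0.90,
mid > 0.80, old otherwise), reflecting the way ">90% identity" is used to
single out young copies in the literature this package serves.

## Events by synteny

Copies in different species are the same duplication event (orthologs) when
their flanking-gene neighborhoods agree; otherwise they are independent
events. The synteny context is the `w = 3` annotated genes on each side of
the locus. Two copies share a side when the longest ordered common
subsequence of flank identifiers reaches `min_shared_flank = 2`, testing
both sides and both orientations (a locus can be annotated on either
strand). Sharing merges transitively, with one guard: an event never holds
two copies from the same species, and merges violating that are refused in
deterministic order. The published analyses state the synteny comparison but
not a window size; `w` and `min_shared_flank` are declared configuration,
not an inference of anyone's intent.

In the pipeline, flank identifiers are gene ids, which the synthetic genomes
make identical for orthologous flank genes. On real annotations one would
map flank genes to family ids (the `gene_families()` clustering) first.

## Gene families

The family stage scores all protein pairs by optimal local alignment and
joins pairs with identity at or above 0.50 whose aligned block covers at
least half the shorter protein (a bare identity threshold would link
trivially short repeats). The graph is clustered by an in-package dense
Markov Cluster implementation: self-loops set to each node's maximum
incident weight, column normalization, then alternating expansion (matrix
squaring) and inflation (elementwise power 2.0, renormalization, pruning
below 1e-8) until the matrix changes by less than 1e-6; clusters are the
connected components of the limit matrix's support. Inflation 2.0 is the
conventional default; the analyses this reproduces do not state theirs, nor
whether edges were weighted by identity, score or E-value — identity is the
declared choice here.

## Phylogenies

Protein sets (parents across species plus functional copies) are aligned
progressively: guide tree from 3-mer distances by neighbor joining, then
profile-profile alignment with affine gaps (open 10, extend 0.1 on BLOSUM62
— ClustalW-like defaults, declared configuration). Trees are neighbor
joining on Poisson-corrected distances (`-ln(1 - p)`) with pairwise deletion;
NJ replaces a maximum-likelihood tree search deliberately — it is orders of
magnitude cheaper, exact on additive distances, and the downstream claims
(parental clades short-branched, duplicate clades long-branched) depend on
branch lengths, not on fine topology. Negative NJ branch lengths are clamped
to zero with the deficit moved to the sister edge. Bootstrap support is the
percentage of 100 column-resampled replicates containing each internal
bipartition, seeded and reproducible.

## Codon models

Selection is quantified by dN/dS (omega) under a Goldman-Yang style 61x61
codon model: kappa scales transitions, omega scales nonsynonymous changes,
equilibrium frequencies are F3x4 (positional nucleotide frequencies — the
common default where the source analyses do not state their frequency
model), and each rate matrix is scaled so branch lengths are expected
substitutions per codon. The likelihood is computed by Felsenstein pruning
over compressed site patterns in C++ (the model is time reversible, so the
matrix exponential comes from one symmetric eigendecomposition per omega
class, and the likelihood is invariant to rerooting — asserted in the
tests). Three model shapes are fitted: `one_ratio` (a single omega),
`one_ratio_fixed1` (omega pinned to 1, the neutral null), and `two_ratio`
(separate omega on designated foreground branches — which branches are
foreground is always an explicit argument, never guessed). Branch lengths,
kappa and free omegas are optimized by L-BFGS-B on the log scale from
starting omegas 0.1 and 1.0; inside simulation loops a single documented
start (0.4) is used instead, because the surface there is unimodal and
restarts only duplicate work. An optional warm start from a nested fit
guarantees the nesting chain numerically. Nested models are compared by
likelihood-ratio tests (2 delta lnL against chi-square; statistics within
0.02 of zero are clamped, larger negative values raise an optimization-
failure error). Reported omega is capped at 999 where dS carries no
information, matching the convention of published tables. Nei-Gojobori
(1986) counting (pathway-averaged, stop-codon pathways excluded,
Jukes-Cantor corrected) is implemented as an independent cross-check, not as
the estimator.

The simulator evolves codons along a tree under exactly the fitted rate
matrix, which is what makes parameter-recovery acceptance checks meaningful:
at 6 taxa and 500 codons, median omega-hat over 20 replicates recovers 0.1
and 0.5 within the tolerances asserted in `tests/testthat/test-acceptance.R`,
and the two-ratio LRT rejects equal-omega data at close to its nominal 5%
over 200 replicates. Those problem sizes (6 taxa, 500 codons, 20/200
replicates) are the package's declared study conditions for these checks.

## Turnover statistics

Group comparisons of duplicate proportions use the pooled-variance
two-proportion Z-test without continuity correction — the only construction
that reproduces the published statistics (Z = 2.7591 from 7/22 vs 1/29,
Z = 2.1164 from 5/22 vs 1/29) from their printed counts, verified
analytically. The pseudogene-rate comparison against a genome-average
baseline is a one-proportion Z-test, one-sided for the "higher" alternative;
the published bound (p < 0.0001) holds under any reasonable sidedness.
No multiple-testing correction is applied, matching the source analyses.

## The synthetic-genome generator

The generator is first-class, tested code: it plants multi-exon parent genes
(random ORFs with GT..AG introns that contain stops in all three frames, so
translated search cannot read through them), conserved flanking filler genes
(identical across the species that share an event — the ground truth for
synteny), and duplicates of every mechanism with tunable protein identity.
Divergence is introduced as amino-acid-changing codon substitutions at
exactly `round((1 - target) * length)` positions plus synonymous swaps at a
configurable rate, so realized identity is within 2 percentage points of
target by construction; there are no indels in functional copies, since the
identity percentages being emulated are substitution-driven. Pseudogenization
replaces the codon `truncation_aa` positions before the parent's stop with
TAA. Tandem copies land within 10 kb downstream of the parent on the same
contig; unlinked copies go to other contigs with their own flanks.
Coordinates are 0-based half-open internally and 1-based inclusive in GFF3.

The bundled demo design (`demo_config()`) is five species, three parents
(2, 4 and 5 exons) and twelve planted copies — four functional retrocopies,
three partial retrocopies, three DNA copies (one tandem), two pseudogenized
retrocopies — spanning identities 0.65 to 0.98 across ten independent
events. Identity targets were placed away from the 0.80/0.90 age-class
boundaries so that class labels are not decided by rounding.

What the generator does **not** emulate: realistic intergenic composition,
transposable elements, codon-usage bias, indel evolution, alternative
isoforms, assembly gaps or annotation errors. Passing the planted-truth
checks therefore demonstrates that the pipeline's logic is correct under
clean substitution-driven divergence — not that its thresholds are optimal
for noisy real assemblies.

## Numerical choices and degenerate inputs

* Alignment tie-breaks are delegated to the pairwise aligner, which is
  deterministic; identities are computed over alignment columns.
* MCL prunes below 1e-8 and stops on a 1e-6 column change; overlapping
  attractor systems are resolved by connected components of the limit
  support (deterministic).
* Poisson distance is undefined at p >= 1 and raises an error suggesting
  p-distance; identical-sequence alignments yield star-like NJ trees with
  zero supports.
* F3x4 frequencies are floored at 1e-8 and renormalized so the rate matrix
  stays irreducible on skewed alignments.
* All randomness flows through explicit seeds; derived seeds are computed in
  double precision and kept below 2^31.
* The run report carries wall-clock timings, so the byte-identity guarantee
  covers every data output and excludes `run_report.json`.

## Limitations

* Search has no E-value statistics; identity and length thresholds stand in
  for them (by design — identity is the criterion the emulated analyses
  printed).
* NJ is not a maximum-likelihood tree search; topologies inside dense
  clades of near-identical copies may be unstable even where branch-length
  conclusions are not.
* The codon machinery covers branch models only — no site or branch-site
  models, and no McDonald-Kreitman tests.
* Event collapsing assumes flank identifiers are comparable across species;
  on real annotations, run the family clustering over flank genes first.
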