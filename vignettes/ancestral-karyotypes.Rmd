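---
title: "Reconstructing pre- and post-WGD ancestral karyotypes with SCJ rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pre- and post-WGD ancestral karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokaryo)
```

## The problem

Three related plant genomes — think of a poppy-like clade — differ by
whole-genome duplications (WGDs): one genome never duplicated, a second one
carries a WGD shared with the third, and the third underwent an additional,
lineage-specific WGD.  Their karyotypes (7, 11 and 22 chromosomes in the
motivating system) were further reshaped by chromosome fissions, fusions and
translocations.  `paleokaryo` reconstructs the ancestral karyotypes before
and after the shared WGD, counts the fissions and fusions that produced the
modern chromosomes, tests whether those events are placed non-randomly,
dates the WGDs from synonymous-substitution (Ks) distributions, and
normalises cross-species expression — the complete computational core of
such a comparative study, exercised end-to-end on a ground-truthed
simulator.

## Genomes, adjacencies and the SCJ model

A genome is a set of linear chromosomes, each an ordered sequence of signed
marker copies (`"+m3.0"` is copy 0 of marker `m3` read forward).  Every copy
has a *tail* and a *head* extremity; consecutive markers on a chromosome
realise an *adjacency* between two extremities.  Telomeres carry no
adjacency, so a genome with $m$ marker copies and $c$ linear chromosomes has
exactly $m - c$ adjacencies.

The single-cut-or-join (SCJ) model scores rearrangement by the elementary
moves "cut one adjacency" and "join two free extremities".  For genomes $A$,
$B$ with identical labelled content the SCJ distance is simply

$$ d_{SCJ}(A, B) \;=\; |\,\mathcal{A}(A) \,\triangle\, \mathcal{A}(B)\,| $$

the symmetric difference of their adjacency sets.  This gives the model its
decisive computational property: problems that are NP-hard under richer
models decompose adjacency-by-adjacency.

* **Median (GMP).** The genome minimising the summed SCJ distance to three
  genomes is exactly the *majority vote*: keep every adjacency present in at
  least two of the three inputs.  Majority sets are conflict-free — two
  adjacencies sharing an extremity would have to co-occur in one of the
  input genomes, which no valid genome allows.
* **Guided halving (GGHP).** Given a doubled genome (two copies per marker)
  and a single-copy outgroup guide, once every marker's copies are assigned
  to post-WGD sub-genomes the optimal ancestor is again a majority vote over
  {sub-genome 1, sub-genome 2, guide}.

Both claims are verified in the test suite against brute-force enumeration
of *all* genomes on up to five markers.

## Copy matching (MO)

The hard part is the assignment the halving step presupposes.  A genome hit
by a WGD carries $2k$ copies of every marker that a guide carries $k$ times;
matching pairs them and labels the pairs against the guide so that the
halving objective

$$ d_{SCJ}(\text{ancestor} \otimes 2 \text{ as paired},\ \text{doubled})
   \;+\; d_{SCJ}(\text{ancestor},\ \text{guide}) $$

is minimal, with the ancestor fixed to the majority vote implied by the
assignment.  Small instances are solved exhaustively (every joint
assignment, bound configurable via `max_exhaustive`), which the tests verify
against an independent enumeration oracle.  Realistic instances use a
deterministic two-stage heuristic:

1. **Propagation seeding.** Walk each chromosome of the doubled genome and
   extend assignments along guide adjacencies; where the guide lacks the
   adjacency (a lineage-specific breakpoint), continue with the same
   sub-genome label — post-WGD chromosomes are contiguous sub-genome
   segments.
2. **Local search.** Alternate sweeps of single-marker reassignments with
   *window moves*: a coherent transform (swap the two sub-genome labels,
   swap the two guide-copy labels, or both) applied to a whole chromosome
   segment.  Only windows bounded by currently misaligned adjacencies are
   tried; flipping inside a fully aligned run can only lose agreement.
   Window moves exist because the objective has large cost-neutral plateaus
   — wherever the guide's two copies are locally identical, per-marker
   moves see no gradient, yet the median downstream needs labels that are
   consistent over whole segments.

All tie-breaks are lexicographic in C-locale order, so reconstruction is
deterministic.

## The pipeline, stage by stage

1. **pPGs.** Ortholog pairs (BlastP-like tables) define a graph on genes;
   its connected components are *putative protogenes* (pPGs).  A pPG is
   *core* when its per-genome member counts equal the WGD-implied ratio —
   1:2:4 for a no-WGD / one-WGD / two-WGD trio.
2. **Painting and blocks.** Each chromosome is rewritten as its sequence of
   signed pPGs.  A pPG-level adjacency is *conserved* when it is realised,
   sign-aware, in every occurrence of both partners across all genome
   copies; conserved adjacencies form a partial matching on pPG
   extremities, and the maximal paths of that matching are the
   non-overlapping synteny blocks.  Blocks shorter than `min_len` pPGs
   (default 3) are discarded; blocks whose copy counts deviate from 1:2:4
   are filtered out; remaining non-core pPGs are filled into blocks when
   every occurrence places them in the same inter-core slot.
3. **Ancestors, bottom-up.** (A) Guided halving of the two-WGD genome
   against the one-WGD guide yields the pre-WGD-2 ancestor.  (B) The no-WGD
   genome is doubled in silico, relabelled against the one-WGD anchor, and
   the SCJ median of the three two-copy genomes yields the post-WGD-1
   ancestor (the karyotype at the second speciation).  A `median_mode =
   "single"` variant lets the outgroup vote label-free instead.  (C) Guided
   halving of that ancestor against the no-WGD genome yields the pre-WGD-1
   ancestor.  Reconstructed adjacency support (votes) is reported
   throughout, and cycles arising in linearization are opened at their
   lexicographically smallest adjacency and logged.
4. **Gene orders.** Within each block a directed graph weighted by how many
   copies realise each immediate precedence is cycle-broken (delete the
   lightest edge per cycle) and greedily topologically sorted, giving the
   pPG order used to expand block-level ancestors back to gene level.
5. **Downstream statistics.** Painting modern chromosomes by ancestral
   protochromosome yields fission counts (carriers of a unit minus one) and
   fusion counts (distinct-unit segments of a chromosome minus one), with
   the bookkeeping identity `modern = ancestral x 2^WGD + fissions -
   fusions` checked and reported; a z-test flags units with significantly
   enriched or depleted events.  Ks values are fitted with an in-house EM
   (k-means initialisation under a fixed seed, BIC model choice), and WGD
   ages follow from $T = K_s/(2r)$ with $r$ calibrated as $K_s/(2T)$ on a
   dated speciation.  TPM matrices are z-scored per species and shifted to
   non-negativity.

```{r example, eval = FALSE}
cfg <- pipeline_config(preset = "papaver-minima", seed = 1)
report <- run_full_pipeline(cfg)
report
```

## The simulator and what it does (not) show

`simulate_three_species_scenario()` generates the full scenario with ground
truth: a six-chromosome ancestor, WGD-1, shared stem rearrangements, the
two speciations, WGD-2, per-branch fissions/fusions/translocations
(replayable event log), optional gene loss (healing the flanking
adjacency), noisy ortholog tables, Ks draws from truncated Gaussian
mixtures and TPM matrices.  The `"papaver-minima"` preset applies the
minimal event counts implied by the three modern karyotypes — 5 fissions /
4 fusions on the no-WGD branch, 11/12 on the shared post-WGD-1 stem, 20/20
after WGD-2 — so the simulated karyotypes are exactly 7, 11 and 22
chromosomes.

Parameters that matter:

* `n_markers` (preset 1000): sets the breakpoint density per marker
  adjacency.  Real genomes carry tens of thousands of genes against a few
  dozen breakpoints; at a few hundred markers the simulation would sit in
  an unrealistically dense regime where independent breakpoints frequently
  strike the same block junction.  When that happens, a junction can lose
  two of its three witnesses and majority voting — correctly, under
  parsimony — drops a true ancestral adjacency; fission/fusion counts inferred from
  extant genomes are always “at least N events” minima for the same
  reason.  1000
  markers keeps such collisions rare while remaining desk-scale (a full
  reconstruction runs in seconds).
* `min_len` (default 3): the minimum block length in pPGs.  Raising it
  discards more short conserved runs (markers near breakpoints), lowering
  recall slightly; lowering it to 1 keeps everything, at the price of
  blocks with no internal order evidence.
* `loss_rate`, `ortholog_noise`: perturb the 1:2:4 structure; core pPGs and
  ratio-conforming blocks then shrink, which the fill-in step and filters
  absorb up to a point.

What passing recovery tests show: the pipeline reconstructs the pre-WGD-1
karyotype (6 chromosomes, adjacency F1 well above 0.9) from rearranged,
twice-duplicated descendants under the preset's event counts.  What they do
not show: robustness to assembly errors, fractionation-biased gene loss,
tandem arrays, or ortholog inference noise at real-data rates — the
simulator's ortholog cliques and uniform event placement are idealisations,
and real applications should read the support votes, the
`bookkeeping_ok` flag and the unplaced-pPG report rather than trust point
estimates.

## Numerical and design choices

* SCJ distance counts internal adjacencies only (no telomere caps); this
  keeps the distance a plain symmetric-difference count.
* Circular chromosomes are not modelled; cycles produced by adjacency
  voting are opened deterministically and reported.
* Genome equality is canonical: chromosomes are unordered and each equals
  its reverse complement; all canonicalisation uses C-locale (radix)
  ordering, independent of the session locale.
* The Ks EM fits untruncated Gaussians to the observed (non-negative)
  values, the standard practice for Ks work; the simulator truncates at
  zero by resampling.  BIC uses $3k - 1$ free parameters.  Rate
  arithmetic is reported at full precision: calibrating with a mean
  interspecies Ks of 0.12 at 7.7 My gives $r = 7.79 \times 10^{-9}$
  substitutions/site/year.
* TPM normalisation uses the population (divide-by-$n$) standard deviation
  over all entries of a species' matrix, and the non-negative variant is
  `TPM_z - min(TPM_z)` — the shift direction that actually achieves
  non-negativity.
* The fission/fusion z-test defaults to a uniform per-unit null, with a
  weight-proportional alternative (`weights =`); p-values are reported
  without multiplicity correction, and the report says so.

## Known limitations

* The copy-matching heuristic carries no optimality certificate above the
  exhaustive bound; on hard instances the reported cost is an upper bound.
  At the preset's scale the exhaustive-vs-heuristic agreement is tested on
  every instance small enough to enumerate.
* Fission/fusion counts from paintings are parsimony minima: a fragment
  re-fused next to its sister segment is invisible, which the
  `bookkeeping_ok` flag surfaces.
* The problem sizes used in the shipped tests (up to 1000 markers, 20
  replicate seeds, 200 brute-force median instances on five markers) are
  the package's chosen desk-scale conditions; they complete in a few
  minutes on one CPU.
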