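---
title: "Identifying G protein-coupling selectivity determinants in aminergic GPCRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying G protein-coupling selectivity determinants in aminergic GPCRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrsel)
library(tibble)
```

## The scientific problem

Aminergic G protein-coupled receptors (GPCRs) — the receptors for
dopamine, serotonin, epinephrine, histamine, acetylcholine and trace
amines — couple selectively to subsets of the eleven Gα subtypes, and
the receptor-side sequence determinants of that selectivity are largely
unresolved. `gpcrsel` implements a phylogenetics-driven pipeline for
finding them, in two arms:

1. **Evolutionary arm.** For each receptor, restrict analysis to true
   orthologs (paralogs experience different selective pressure), score
   per-column conservation with substitution tolerance, and contrast
   receptors that couple to a given Gα ("couplers") against those that
   do not, to find *specifically conserved* positions — conserved in
   couplers, occupied by dissimilar or weakly conserved residues in
   non-couplers.
2. **Structural arm.** Quantify residue-residue contact scores (RRCS)
   in active versus inactive receptor structures, build the common
   activation network shared across receptors, and test per-edge
   contact changes (ΔRRCS) between coupler groups (ΔΔRRCS) to expose
   Gα-specific activation mechanisms. MD trajectory frames are analysed
   the same way to compare wild-type and mutant dynamics.

Because the original inputs (UniProt retrievals, PDB entries, deposited
trajectories) are external, the package ships first-class synthetic
generators that emulate each input with known planted ground truth.
Every statistical component is validated against that truth.

## Ortholog selection and paralog trimming

A gene tree over the homologs of a human target receptor is rooted on
an outgroup — by convention the third human protein found in the
homolog search (`root_by_outgroup()`). `extract_ortholog_clade()` then
walks from the target leaf toward the root; each newly joined sibling
clade is included if its species have not been observed before, and
excluded (reason `reseen_species`) otherwise, since re-seeing a species
at a lower level of the tree indicates differential gene loss rather
than orthology. The walk stops at the first clade containing another
human protein: that node marks the duplication boundary. Two
conventions are deliberate: species observed in *excluded* clades do
not poison later steps (only retained sequences define "observed"), and
a duplicate species *within* a single joined clade does not trigger
exclusion — only cross-step re-sighting does.

`trim_paralogs()` removes diverged paralogous clades that survive the
walk. Every leaf is scored against the human target by global
Needleman–Wunsch alignment under BLOSUM62 (gap open 11, extend 1; only
the matrix is prescribed by the method — the penalties are
EMBOSS/BLAST-like defaults). Internodes are assessed leaves-up in
post-order; a removed clade is excluded from later assessments. At an
internode whose children share at least one species:

* with at least three leaves per side, the clades must be
  *evolutionarily comparable* — a two-sample t-test on each leaf's
  count of taxonomic ranks shared with the human lineage must not be
  significant (p > 0.1); if comparable and the score t-test gives
  p ≤ 0.1, the lower-mean clade is removed;
* with fewer than three leaves on both sides, the lower-average clade
  is removed outright;
* mixed sizes remove nothing.

The t-tests are classic two-sided equal-variance Student tests (Welch
is available via `var_equal = FALSE`); "significantly lower" is
enforced by the post-hoc mean comparison. The method text does not fix
sidedness or variance treatment; two-sided Student plus the mean check
is the most conservative reading. Zero-variance samples (exactly
constant noise-free fixtures) are handled explicitly: equal constant
samples give p = 1, different constant samples p = 0. A clade removal
that would delete the target itself raises a diagnostic error rather
than proceeding.

`simulate_paralog_tree()` generates the matched fixture: an ortholog
clade around the target and a sibling paralog clade with overlapping
species, whose sequences carry extra divergence `1 - exp(-d)`
substitutions per site. At `d = 0` the clades are exchangeable, so
removals are pure type-I errors; the calibration tests require the
false-removal rate over 100 seeds to stay within [0, 0.15] at the
nominal 0.1 (counting the target-clade diagnostic as the other half of
the same two-sided event), and removal power at `d = 1` to reach 0.95.

## Conservation with substitution tolerance

`column_conservation()` implements the tolerance-credited conservation
score. For one alignment column: find the most frequent residue; every
other residue whose BLOSUM80 score against it is *strictly greater
than 2* is an "allowed" substitution; the score is the fraction of
non-gap rows holding the modal residue or an allowed substitute.
Columns with strictly more than 50% gaps are flagged as gap positions
and not scored. Three tie-break/edge conventions are fixed: modal ties
resolve by alphabetical amino-acid order; `X` counts in the non-gap
denominator but can be neither modal nor allowed; "higher than 2" is
read strictly (an integer score of exactly 2 earns no credit). The
implementation is tested for exact integer-ratio equality against an
independent brute-force recount on 1,000 random columns.

## Specificity classification

`classify_position()` labels a column shared by two families from their
conservation profiles, with thresholds 90% (specificity), 90%
(consensus) and 70% (lower bound on the opposing family), all strict:

* `gap` if either side is gap-flagged;
* `consensus` if both sides exceed 90% and the modal residues are
  similar (BLOSUM80 > 1);
* dissimilar modals (BLOSUM80 < 2): each side above 90% earns its
  specific label (possibly both);
* similar modals: a side is specific only if it exceeds 90% while the
  other falls below 70%;
* otherwise `none`.

The stated cutoffs overlap at a BLOSUM80 score of exactly 2 (pairs such
as L/M, E/Q, K/R): the package treats 2 as "similar" in both the
consensus and the specificity branch, the only self-consistent reading
of "more than 1" and "lower than 2" together. An exhaustive truth-table
test enumerates every branch combination.

## Two-step enrichment

For one Gα subtype with *n* coupler and *m* non-coupler receptors:

* **Specific approach** (`specific_approach()`): classify every
  coupler/non-coupler family pair (n·m ordered comparisons) and record
  the per-column frequency of coupler-side specific calls; do the same
  over the n·(n−1) ordered coupler/coupler pairs. A column is reported
  only when the cross frequency is positive and the within frequency is
  exactly zero — no inside variation tolerated. Ordered pairs are used
  because the comparison count is n·(n−1); the zero/non-zero decision
  is identical under unordered counting.
* **Sensitive approach** (`sensitive_approach()`): pool all coupler
  receptors and their orthologs into one comprehensive alignment
  (`combine_families()`) and compare that against each non-coupler
  family, reporting columns specific in more than a configurable
  fraction of the m comparisons (default: more than zero, mirroring the
  specific approach). Pooling tolerates minor within-group variation,
  including false-positive couplings in the profile datasets. The
  sensitive approach is masked for G12/G13 by default
  (`pipeline_config(sensitive_mask = )`), where very few couplers would
  inflate false positives.

The interlock between the two approaches is sharpest at the BLOSUM80
boundary score of 2: a coupler family carrying a minority of such a
"similar but not allowed" variant (e.g. M against modal L) drops below
the 70% lower threshold, turns the coupler/coupler comparison into a
specific call, and is therefore dropped by the specific approach — yet
the pooled alignment keeps the modal residue above 90% and the
sensitive approach recovers the column. This constructed fixture is a
deterministic regression test.

Coupling profiles come from a per-source table
(`coupling_table()`); because published coupling datasets disagree for
some receptors, the coupler/non-coupler split applies a source policy
(`union` by default, `intersection` or a single named source
otherwise). Consensus positions across all families
(`consensus_positions()`) require the consensus label in every pairwise
comparison by default (configurable fraction), and
`merge_residue_sets()` pools specific, sensitive and consensus
positions with provenance tags.

## RRCS, ΔRRCS and activation networks

`compute_rrcs()` scores each residue pair by summing, over its
heavy-atom pairs, a piecewise-linear weight in the interatomic
distance: 1 at or below 3.23 Å, 0 at or beyond 4.63 Å, linear between.
For residue pairs fewer than 5 positions apart in sequence, atom pairs
involving a backbone atom (N, CA, C, O) are excluded so bonded
neighbours do not register. These constants follow the published RRCS
method and are all exposed as arguments. The implementation is verified
against a brute-force double loop to 1e-9 on random 20-residue
structures.

`delta_rrcs()` forms ΔRRCS = RRCS(active) − RRCS(inactive) per pair
(a missing pair contributes zero), so *positive means a contact formed
on activation* — the sign convention of the network figures; edges with
|ΔRRCS| ≤ 0.2 are dropped (a 1e-9 numeric tolerance makes the boundary
exact under floating-point subtraction), and edges are restricted to
the pool of conserved residues (both endpoints by default, either-end
optional). `common_network()` keeps edges present in at least 36 of the
networks regardless of sign, mirroring the 36-of-41 structure-pair rule;
`pairing_plan()` accepts an explicit pair list because a published pair
roster need not equal the per-receptor Cartesian product.
`gprotein_specific_network()` compares a coupler group's per-pair ΔRRCS
values against all remaining pairs edge-by-edge with a two-sample
t-test (α = 0.01 for most subtypes, 0.1 for Gi1), annotating retained
edges with the ΔΔRRCS mean difference and sign; an exclusion list
supports re-testing with an outlier receptor (or single structure)
removed.

## Trajectory contact analysis

`sample_frames()` picks the frame nearest each target time on the
inclusive grid 0, 50, …, 500 ns — 11 frames per replicate, hence 77
frames over 7 active replicates and 22 over 2 inactive replicates.
`contact_change_test()` computes per-frame RRCS and tests each residue
pair two-sidedly between WT and mutant frame sets; the default α is
0.05 per the stated testing procedure, while the stricter 0.01 used
when reporting common changes can be applied downstream from the
returned p-values (`intersect_common_changes()` then keeps edges
significant in every mutant, recording per-mutant signs).
`classify_state()` computes the GPCRdb activation metric
d(2x41–6x38) − d(3x44–7x52) from Cα atoms — the atom choice is not
specified by the method text; Cα is the convention here — and calls a
frame active above 7.15 Å, inactive below 2 Å, intermediate otherwise,
with both inequalities strict so the boundary values themselves are
intermediate.

## What the synthetic generators do and do not emulate

All generators are pure functions of a spec plus seed and emit their
planted truth alongside the data.

* `simulate_family()` / `simulate_cohort()` use i.i.d. per-column
  substitution with no phylogenetic correlation — sufficient to
  exercise the scoring arithmetic, but real MSAs have correlated
  residues, indel structure and rate variation, so passing recovery
  tests demonstrates correctness of the method's logic, not performance
  on real alignments. Default cohort conditions: 3 couplers, 3
  non-couplers, 12 orthologs per family, 60 columns, 3 planted
  determinants, 2% substitution noise for the recovery experiments.
* `simulate_paralog_tree()` plants one diverged clade with
  species overlap; clade sizes 6+6 and sequence length 120 keep 100-seed
  calibrations cheap while leaving the t-tests properly powered.
* `simulate_structure_pair()` places one side-chain pseudo-atom per
  residue on a 12 Å lattice (RRCS legally operates on whatever heavy
  atoms exist); planted contacts form at 3.0 Å and break at 5.5 Å.
  Real structures have many atoms per residue and correlated motions.
* `simulate_trajectory()` interpolates between two templates with
  Gaussian coordinate noise; it has no force-field realism. A built-in
  mid-ramp (3.9 Å) contact makes per-frame RRCS genuinely
  distance-sensitive, which is what the WT-vs-WT null calibration
  (retention ≤ α + 2·SE over 200 seeds) exercises.

## Numerical choices and degenerate inputs

* Strict threshold comparisons throughout (90/90/70%, BLOSUM80 > 2,
  gaps > 50%, |ΔRRCS| > 0.2, metric > 7.15 / < 2).
* Zero-variance t-test samples: p = 1 when means are equal, 0
  otherwise.
* Modal-residue ties: alphabetical order; equal clade means under the
  small-clade rule: no removal.
* Structures: hydrogens/deuteriums dropped; highest-occupancy altloc
  kept (first record on ties); duplicate atom serials warned and
  deduplicated; a structure without Cα atoms is rejected.
* Columns with only `X`/gap content receive no conservation score and
  classify as `none`/`gap`.

## Problem sizes used by the test-suite experiments

Recovery and calibration experiments run at 50 seeds (cohort
enrichment), 100 seeds (paralog trimming, each arm) and 200 seeds
(null calibrations of the group and trajectory tests); oracle
equivalence uses 1,000 random columns and five random 20-residue
structures. These sizes give binomial standard errors small enough for
the stated bounds while keeping the default suite quick to run.

## Known limitations

* The evolutionary arm assumes per-receptor ortholog MSAs share a
  common column coordinate system (or an explicit column map); building
  that joint alignment is upstream of this package.
* Generic numbers are consumed as an input map, never computed; mapping
  quality is the caller's responsibility.
* The i.i.d. generators cannot expose failure modes driven by
  phylogenetic autocorrelation; conclusions about real-data performance
  require real alignments.
* With very few coupler receptors the specific approach's
  inside-variation rule becomes brittle and the sensitive approach is
  deliberately unavailable for G12/G13-like cases, so those subtypes
  rest on the specific approach alone.

## A minimal worked run

```{r example}
cohort <- simulate_cohort(cohort_spec(seed = 42))
spec_res <- specific_approach(cohort$couplers, cohort$noncouplers,
                              g_protein = "Gs")
spec_res
cohort$truth$planted_columns
```

```{r structures}
pair <- simulate_structure_pair(structure_pair_spec(
  12, planted_gain_pairs = list(c(2, 9)), seed = 1))
dnet <- delta_rrcs(compute_rrcs(pair$active), compute_rrcs(pair$inactive),
                   pool = unique(pair$active$generic_number))
tidy(dnet)
```
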