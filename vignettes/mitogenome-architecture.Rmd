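---
title: "Methods: mitogenome architecture, TDRL rearrangements, and character mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome architecture, TDRL rearrangements, and character mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
behind `mitoarch`. It states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` compute.

## Coordinate and annotation conventions

Coordinates are 1-based and fully inclusive, so a feature at 1–68 spans 68
bases; a feature may wrap the circular origin, in which case its size is
`genome_length - start + 1 + end`. The intergenic spacer after a feature is
`next_start - prev_end - 1`; negative values denote overlap. On a circular
record, feature sizes and spacers (including the wrap-around spacer)
telescope exactly to the genome length — the test suite asserts this
conservation law on every generated record.

Minus-strand genes are stored with their heavy-strand coordinates as
annotated; orientation is applied only when sequence is extracted
(`feature_sequence()` reverse-complements). Annotation inconsistencies
(printed size vs. computed size, printed amino-acid counts vs. coordinate
arithmetic, nonstandard anticodons, gene-count anomalies) are surfaced as
data by `validate_record()`, never silently corrected: the packaged
reference tables are kept verbatim, inconsistencies included, so the
validator's findings are themselves reproducible facts about the source
annotations.

## Composition and skew statistics

GC-skew = (G − C)/(G + C) and AT-skew = (A − T)/(A + T) are scale-invariant,
so they can be computed equivalently from raw counts or from printed
percentages; the tests assert both routes agree. The scalar `gc_skew()` /
`at_skew()` raise an error on a zero denominator; `region_composition()`
instead reports `NA` for a degenerate region so that the remaining
statistics stay available. Ambiguity codes are excluded from counts and
denominators. Region classes are PCGs, rRNA, tRNA, control, and genome;
regional sequences are strand-oriented by default.

## Codon analysis

The genetic code is fixed to the vertebrate mitochondrial code (AGA/AGG
stops, ATA = Met, TGA = Trp); the test suite cross-checks all 64 codons
against an independent implementation. Incomplete stop codons (`T-`, `TA-`)
are completed to TAA before translation, and
`amino_acid_length(size, stop) = (size - stop_len)/3 - 1` (minus the
stop) must be integral — a frame inconsistency is an error, which is how
one of the reference annotation's size anomalies manifests. RSCU is
`count * family_size / family_total` with stop codons excluded; zero-total
families are flagged rather than divided.

## TDRL rearrangement model

A TDRL round on a gene order duplicates a contiguous block in tandem and
then deletes copy indices from the expanded order; deleting the last copy of
any gene is an error (letter retention). `minimal_scenarios()` enumerates
all minimal-round event histories from a source to a target order.

Numerical choice: the search enumerates only canonical scenarios in which
every round before the last is a pure duplication (no losses), with all
losses deferred to the final round. This is exhaustive for minimality: any
scenario can be rewritten round by round — a loss whose position falls
outside the next round's block commutes forward unchanged, and a loss inside
the next block is absorbed by widening that block and deleting both copies —
without changing the derived order or the number of rounds. The test suite
validates the search against a brute-force oracle that enumerates every
block and every loss subset (bitmask), on exhaustive target sets for small
sources and stratified random targets for the five-gene cluster. Scenario
lists are returned sorted (fewest losses first) with the minimum round count
as an attribute, and every returned scenario replays to the target via
`apply_tdrl()`.

Cluster extraction takes the tRNAs strictly between ND2 and COI; pattern
classification is an exact letter match against the named orders (WANCY,
WYANC, WNCYAC, WNCYAA), else OTHER.

## tRNA pair classification

Structures are consumed (dot-bracket + sequence), never predicted. Pairs are
classified by unordered base set: {A,U}/{G,C} Watson–Crick, {G,U} wobble,
{A,C} its own class, anything else "other", so the classes always partition
the pairs. T and U are equivalent on input.

## Character mapping

`fitch_parsimony()` implements the generalized (Hartigan-style) downpass —
at each internal node the states with maximal child votes are kept and the
step count grows by (children − max votes). Unlike iterated pairwise
intersection/union, this is exact on multifurcations, which matters because
the packaged reference tree contains unresolved nodes. The tests check it
against an exhaustive internal-labeling oracle and (where available) an
independent parsimony implementation on bifurcating trees.

`tip_permutation_test()` shuffles tip states (`n_perm` ≥ 99, default 999)
and reports `p = (1 + #{permuted steps ≤ observed}) / (1 + n_perm)`; the
caller's RNG state is saved and restored. A constant character yields a
warning and p = 1. `character_concordance()` cross-tabulates two tip
characters and flags perfect association (each state of the first maps to
exactly one state of the second).

## Synthetic generator

`generator_spec()` defaults are the package's reference conditions: a
16,800 bp circular genome; 13 PCGs with realistic fixed sizes, start codons
(ATG, GTG for COI) and per-gene stop tokens including incomplete stops; two
rRNAs; 22 tRNAs (23 when the requested cluster pattern carries a duplicate);
an origin of light-strand replication inside the cluster; and a control
region absorbing the slack. All features abut, making the conservation law
exact. Per-region base-composition targets default to values typical of a
fish mitogenome; `codon_at_bias` (default 2) up-weights A/T-ending sense
codons to emulate the third-position preference of fish mitochondrial PCGs.

Composition realization is quantized rather than sampled, so that analysis
recovers the targets to rounding precision instead of multinomial noise:

- Non-coding stretches draw their base counts by largest-remainder
  quantization of `n × target`, then permute the order.
- PCG bodies come from a single pooled codon multiset: codon weights over
  the 60 sense codons are fitted by iterative proportional fitting so the
  codon mixture's base marginals equal the region target (after subtracting
  the fixed start/stop bases), then codon counts are quantized, shuffled,
  and dealt to genes. Infeasible targets fail loudly.
- tRNAs are built in two phases because stems constrain composition: a
  Watson–Crick pair always contributes a base and its complement, so stems
  alone cannot realize a skewed target. Stems (21 pairs per tRNA, with the
  requested G-U and A-C counts planted) are generated first; the loop bases
  of all tRNAs are then allocated as one quantized pool that tops the
  region up to its target.

Every planted quantity — pattern, per-region realized counts, per-PCG
start/stop/amino-acid counts, per-tRNA structures and pair counts — is
recorded in a ground-truth ledger, and the test suite re-analyses generated
records against it across dozens of seeds (recovery tolerance ±0.02 on
proportions, exact on integer counts). All randomness is governed by the
spec's single seed; the caller's RNG state is restored.

`generate_labeled_tree()` produces tip-state maps that are either clustered
(one monophyletic clade per state, so Fitch steps = states − 1 by
construction) or random, for calibrating the permutation test.

## Pipeline

`run_pipeline()` chains parse → validate → composition → codon usage →
cluster classification → minimal-TDRL search → character mapping, skipping
sequence-dependent stages for coordinate-only records and the phylogenetic
stage (with a logged notice) when no tree/characters are configured. Outputs
are deterministic given the configuration and seed; the manifest lists every
file with its MD5 hash.

## Problem sizes and limitations

- The TDRL search is exponential in rounds and block placements; the
  package's intended scale is the five-gene WANCY cluster at ≤ 2–3 rounds
  (sub-second). It is not a general genome-rearrangement solver and does not
  model inversions or transpositions.
- Generated tRNAs are uniform 69-nt cloverleaves; real tRNAs vary in arm
  lengths, and the generator makes no claim of structural realism beyond
  pair-class accounting.
- The exhaustive Fitch oracle used in tests is limited to ~10 tips; the
  package algorithm itself scales linearly in edges.
- The permutation test permutes tips freely (no phylogenetic
  signal-preserving null); with 999 permutations the smallest attainable
  p-value is 0.001.
- Composition statistics treat only unambiguous A/C/G/T; records parsed
  without sequence support coordinate arithmetic and validation but not
  composition or codon analysis.
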