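---
title: "Residue-residue connection graphs: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-residue connection graphs: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrcnet)
```

This vignette is the package's own account of what it computes and why the
conventions are the way they are. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The connection model

A protein sequence of length $L$ is a vertex set $v_1, \dots, v_L$.
Around a **residue pair of interest** $(p, q)$ with $p < q$, a bipartite
template — an ordered set of integer offsets $(a, b)$ — realizes the global
connections $(p + a,\; q + b)$, one per template edge. Around a **single
residue of interest** $c$, a window of half-width $w$ maps slot
$s \in 0..2w$ to residue $c - w + s$, and a unipartite template over slots
realizes the local connections. Templates are pure index arithmetic: no
structural distance cutoff is involved, which is exactly what makes the
realization $O(1)$ per edge and the whole assignment linear in the number
of centers.

Count identities, each checked against brute-force enumeration in the test
suite:

| object | count |
|---|---|
| pairs of interest at separation $\ge 1$ | $L(L-1)/2$ |
| patch template, half-width $w$ | $(2w+1)^2$ |
| cross template | $4w+1$ |
| memconp template | $25$ (fixed) |
| complete unipartite template | $(2w)(2w+1)$ |

The complete unipartite count is read as **ordered** pairs of distinct
slots: $(2w)(2w+1)$ equals the number of ordered non-self pairs among
$2w+1$ slots, which is the only reading under which the printed formula is
an integer identity. Connection order is lexicographic in the template
coordinates (the memconp template keeps its canonical published order), so
feature columns are stable across runs and machines.

A related counting convention deserves a note: one could also tabulate
window-placed global connections as (window positions) $\times$ (per-row
edges). We do not enforce any such product formula; the realized connection
count is always exactly the template's edge count $t$, which is the
property downstream feature matrices rely on.

## Boundary policy

A realized connection whose end falls outside $1..L$ is kept, with the end
replaced by an `NA` placeholder, rather than dropped. Rationale: machine
learning consumers need fixed-width rows; a length-$t$ template must yield
exactly $t$ feature columns for every center, including centers near the
termini. At assignment time placeholder-ended connections receive
`placeholder_value` (default 0, neutral under summation and user-settable).
The memconp template additionally requires its two ends to be distinct
residues; a realization that collapses onto a single residue (possible only
for very close central pairs) is emitted placeholder-valued, again
preserving length.

## Feature assignment: two routes, one contract

`assign_hash()` generates each center's connections on the fly and performs
one subscripted read per connection into the dense $L \times L$ matrix —
constant-time keyed lookup, nothing corpus-wide materialized.
`assign_materialized()` first builds the full 3D connection object
(edges $\times$ centers $\times$ 2 end positions) and then looks up. The
two must agree element-wise; the suite checks this over 100 seeded random
configurations spanning every template family ($L \in 20..80$, patch and
cross at $w \in 1..3$, memconp, complete windows at $w \in 1..3$).

Because each route counts its matrix lookups, the linearity claim is
checked by **counting, not timing**: for a fixed template the lookup count
is (centers) $\times$ $t$, and the fitted log–log slope of lookups versus
center count is exactly 1. Wall-clock benchmarking is deliberately out of
scope — it measures hardware, not the algorithm.

## cumuCC

For a correlation matrix with entries $m_{ij}$ (symmetric access, zero
diagonal, absent pairs 0, negative values allowed as coupling estimators
can emit them):

$$\mathrm{cumuCC}_R = \frac{\mathrm{CC}_R}{c}, \qquad
c = \frac{\sum_{i<j} m_{ij}}{L(L-1)/2},$$

where $\mathrm{CC}_R$ sums, over the $k$ globally highest-ranked pairs,
the scores of those pairs containing $R$. Conventions, each a deliberate
choice:

- **$k$ parameterization**: $k = \lfloor \mathrm{ratio} \cdot L \rfloor$,
  floored at 1 and capped at $L(L-1)/2$; ratios of practical interest are
  0.2–10 (selection depths of $L/5$ up to $10L$).
- **Global versus per-residue selection**: the canonical score ranks all
  pairs once, globally; this matches how the sum-of-top-couplings feature
  is used by interface-residue predictors. A per-residue variant (each
  residue ranks its own $L-1$ partners) is exposed as `per_residue = TRUE`
  but is not part of the package's verified surface beyond its unit test.
- **Ties** in the ranking break by ascending $(i, j)$ — determinism over
  any statistical motive.
- **Degenerate input**: $c = 0$ (all-zero or exactly cancelling matrices)
  raises an undefined-normalization error rather than returning infinities.

Two structural identities follow and are tested: positive rescaling of the
matrix leaves the scores unchanged (selection, $\mathrm{CC}_R$ and $c$ all
scale together), and $\sum_R \mathrm{CC}_R$ equals twice the selected-pair
score total (each selected pair contributes to exactly two residues).

## Topology conventions

Region codes follow the PDBTM/TMDET vocabulary: `H` helix, `B` strand,
`C` coil, `I` membrane-inside, `L` loop, `F` interfacial, `U` unknown,
`1`/`2` membrane sides. Structure-derived annotations locate membrane
spans but not which side is cytoplasmic; `redistribute_nontm()` stacks
each non-membrane segment (`1`, `2`, `L`, `U`) against an externally
predicted inside/outside/TM segmentation and takes the label covering the
majority of the segment's residues (inside → cytoplasmic, outside →
extracellular). Membrane-associated codes (`H`, `B`, `F`, `I`, `C`) pass
through untouched, because only non-membrane topology is ambiguous.

Open points resolved here: redistribution operates **per segment**, not
per residue, when a predicted boundary bisects a structural segment — the
segment is the annotation unit and splitting it would invent boundaries
the structure does not support; majority is counted over residues with
ties going to `unknown` (conservative — no evidence, no label). Segment
boundaries are never altered, only codes. Predicted topologies are consumed
as three-column tables rather than by running a predictor: external
binaries are out of scope.

Per-residue encoding (`per_residue_topology()`) gives uncovered residues
`U` and resolves overlaps by last-in-document-order with a warning, the
reading order a curator would expect from an XML file.

## Structure-to-sequence mapping

Crystallographic structures resolve a subsequence of the deposited FASTA
sequence, with gaps and occasional engineered point differences.
`map_residues()` reconciles the two by global Needleman–Wunsch alignment
with identity scoring — match $+1$, mismatch $-1$, affine gaps costing
$\mathrm{open} + n \cdot \mathrm{ext}$ with open $= 2$, ext $= 1$ per gap
position. No substitution matrix: the sequences derive from the same
protein, so a mismatch means an engineering artifact, not homology, and is
mapped but flagged. Gap columns populate the unmapped lists. The forward
(structure number → FASTA position) and reverse maps are mutually inverse
on their shared support, and forward is strictly increasing because global
alignment preserves order.

One well-posedness caveat the recovery tests respect: under identity
scoring a deletion gap can slide score-neutrally when the letter entering
the gap equals the letter leaving it, or when two gaps are close enough
that the intervening segment can shift between them. In those cases "the
original position" of a surviving residue is genuinely ambiguous. The
synthetic recovery trials therefore construct deletions with unequal
boundary letters and at least 12 kept residues between gaps, making the
optimal alignment unique; under that construction 100% recovery is required
and achieved.

## The synthetic-fixture generator

`generate_fixtures()` emulates the study's input shapes at desk scale:

- sequences drawn uniformly over the 20 canonical amino acids (default
  $L = 60$; the acceptance script uses $L = 200$ for topology and
  $L \le 300$ for mapping trials);
- correlation matrices with independent uniform$(0,1)$ pair scores plus
  `n_spiked` (default 10) pairs shifted upward by 1 — a minimal stand-in
  for the heavy right tail of real coevolutionary matrices;
- topology as alternating side1 / 21-residue helix / side2 / helix blocks
  (21 residues is a typical membrane-spanning helix; 9-residue loops),
  with the predicted inside/outside/TM table agreeing by construction
  except for labels flipped independently at `corruption_rate`;
- QC tables with randomized method, resolution, length and helix
  statistics.

One seed governs the whole bundle and is logged in the manifest;
regeneration is byte-identical. What the generator does **not** emulate:
residue composition bias, correlated coupling structure (real matrices are
far from i.i.d.), topology grammar constraints beyond strict alternation,
insertion codes, or multi-chain interfaces. Passing tests on these
fixtures therefore demonstrates algorithmic correctness — counting
identities, route equivalence, label recovery under a known ground truth —
not predictive performance on real proteins.

## Problem sizes and runtime posture

The suite runs the full worked examples plus: counting identities for
$w \in 0..5$ (and 0..6 for the patch) with $L$ swept over $2..200$; 100
equivalence configurations; 50 mapping trials at $L \in 50..300$; 200-record
QC monotonicity sweeps. These sizes were chosen so each property is
exercised across its qualitatively distinct regimes (degenerate $w = 0$,
boundary-truncated, interior) while the whole suite stays interactive —
a property check that takes minutes gets run less often and protects less.

## Known limitations

- Graphs are sequence-index-based only; no structure-derived contact
  definition (heavy-atom distances) is offered.
- The correlation matrix is an input; the package computes no couplings
  (no DCA or mutual-information inference).
- Insertion codes in structure numbering are outside the data model;
  records are consumed in file order.
- Biological-assembly reconstruction, database cross-referencing and
  visualization are out of scope.
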