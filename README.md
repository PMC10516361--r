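# rrcnet

Residue–residue connection graphs and feature engineering for
transmembrane-protein sequence analysis.

## The problem

Contact prediction and interaction-site identification improve markedly when
a model sees not just a residue (or residue pair) of interest but its
*neighborhood*: the scores of surrounding residue pairs in a coevolutionary
coupling matrix. Enumerating those neighborhoods naively is expensive — a
protein of length *L* has *L(L−1)/2* unordered residue pairs (≈125,000 at
*L* = 500), each carrying a template of neighboring connections.

rrcnet treats neighborhoods as graphs over sequence positions:

- **GlobRRCs** (global residue–residue connections): around a central pair
  *(p, q)*, a *bipartite template* of integer offsets *(a, b)* realizes the
  connections *(p+a, q+b)* in contact-map context. Built-in templates:
  the **patch** (all *|a|, |b| ≤ w*, so *(2w+1)²* edges — the 5 × 5 patch at
  *w* = 2), the fixed 25-offset **memconp** helix-packing template, and the
  **cross** (central row + column, *4w+1* edges).
- **LocRRCs** (local residue–residue connections): inside a sliding window
  of half-width *w* on a single residue, a *unipartite template* connects
  window slots; the complete template yields all *(2w)(2w+1)* ordered pairs
  of distinct slots.

Features are assigned by direct constant-time keyed lookup into the dense
correlation matrix, one lookup per connection, so total work is **linear in
the number of centers** for a fixed template. A slower reference route that
first materializes the full 3D connection object is included and must agree
element-wise.

On top of this sits the **cumuCC** score per residue *R*:

```
cumuCC_R = CC_R / c
```

where *CC_R* is the sum over the *k* globally highest-ranked pair scores of
those pairs containing *R* (with *k = ⌊ratio·L⌋*), and *c* is the mean pair
score over all *L(L−1)/2* pairs. Supporting modules handle PDBTM-style
topology XML (parsing, relabeling non-membrane segments as
cytoplasmic/extracellular against a predicted topology, per-residue
encoding), structure↔FASTA residue mapping by global alignment, sequence
windowing, quality-control filters, and a seeded synthetic-fixture
generator.

## Worked example

```r
library(rrcnet)

td <- file.path(tempdir(), "demo")
fx <- generate_fixtures(td, seed = 42, L = 60, n_proteins = 1)

cm <- load_correlation_matrix(fx$correlation[1], L = 60)
cm
#> correlation matrix: L = 60, 1770 nonzero pairs

pairs <- enumerate_pairs(60, min_sep = 5)   # 1540 pairs of interest
ft <- assign_hash(pairs, make_patch(2), cm)
ft
#> feature table: 1540 centers x 25 connection features (38500 matrix lookups)
ft$centers[500, ]; round(ft$values[500, 1:6], 3)
#>      p  q
#> 500 10 55
#> f_000 f_001 f_002 f_003 f_004 f_005
#> 0.127 0.649 0.690 0.032 0.920 0.207

res <- cumucc(cm, ratio = 2)                # k = 2L = 120 top pairs
res
#> cumuCC over 60 residues: k = 120 pairs selected globally, c = 0.493308
round(head(res$scores), 3)
#> [1]  9.605  3.810  7.838  7.809 12.434 11.803

segs <- parse_topology_xml(fx$topology)
head(segs, 4)
#>   chain beg end code
#> 1     A   1   9    1
#> 2     A  10  30    H
#> 3     A  31  39    2
#> 4     A  40  60    H
redistribute_nontm(segs, read_predicted_topology(fx$predicted[1]))$code
#> [1] "cytoplasmic"   "H"             "extracellular" "H"
```

Each feature row holds the 25 patch-neighborhood coupling scores of one
residue pair (placeholder 0 where the patch runs off the sequence); the
cumuCC vector says how much of the globally strongest coupling mass each
residue carries, in units of the average pair score; the topology call turns
structure-derived membrane-side labels (`1`/`2`) into
cytoplasmic/extracellular annotations by majority vote against the predicted
inside/outside segments.

A command-line front end wraps every operation
(`system.file("exec", "rrcnet", package = "rrcnet")`); see
`rrcnet_main("--help")` or the `rrcnet` script for subcommands
(`pairs`, `globrrc`, `locrrc`, `assign`, `cumucc`, `topo-parse`,
`topo-redistribute`, `qc`, `map`, `fixtures`).

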