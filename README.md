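# surfcamd

Computer-aided molecular design of surfactants by head–tail
decomposition: exhaustive enumeration of hydrophilic-head and
hydrophobic-tail molecular graphs from building-block group tables,
assembly into full surfactant SMILES, linear QSPR property prediction,
and ε-constraint multiobjective ranking with TOPSIS.

## Who this is for

Formulation and molecular-design researchers who want to screen a
*complete*, constraint-defined space of candidate surfactants — rather
than optimize inside a coupled structure/property program — and rank the
candidates against both performance properties (critical micelle
concentration, surface tension, Krafft point) and environmental ones
(aquatic toxicity as log LC50, ready biodegradability, synthetic
accessibility).

## The model at the core

A fragment (head or tail) is a graph over group instances. Each group
*j* carries a valence *v<sub>j</sub>* (free attachment points), declared
connection atoms, and an occurrence limit *n<sub>j</sub>*; single-valence
instances of one type are collapsed into a node of valence equal to the
instance count. A fragment is any symmetric non-negative integer bond
matrix *y* with

- Σ<sub>j′</sub> y<sub>jj′</sub> = v<sub>j</sub> (valence saturation),
  y<sub>jj</sub> = 0,
- y<sub>jj′</sub> ≤ 1 between multivalent nodes,
  y<sub>jj′</sub> ≤ v<sub>j</sub> − 1 toward collapsed nodes,
- Σ<sub>j,j′∈S</sub> y<sub>jj′</sub> ≤ 2|S| − 1 for every multivalent
  subset with |S| ≤ ⌈(m+1)/2⌉ (anti-cycle constraints; their count is
  Σ<sub>i≤Jm</sub> C(m, i)),
- breadth-first-search connectivity (authoritative post-filter).

All solutions are enumerated exactly, with integer cuts guaranteeing no
repeats; every head×tail pair is then fused at the dummy (`*`) atoms at
the atom level (implicit hydrogens consumed at declared connection
atoms), sanitized against standard valences, and canonicalized.
Candidates are scored by affine QSPR models (PLS or cross-validated
lasso over filtered 2D descriptors) and ranked by ε-constraint
enumeration → Pareto filter → TOPSIS closeness.

## Worked example

Enumerate a small head space (sulfate or hydroxyl head groups with up to
two methylene spacers) and a heptyl tail, then assemble:

```r
library(surfcamd)

heads <- generate_all(group_set(list(
  group_spec("dummy", "*", 1),
  group_spec("sulfate", "OS(=O)(=O)[O-]", 1),
  group_spec("methylidene", "C", 2, max_occurrences = 2),
  group_spec("hydroxyl", "O", 1)),
  role = "head", min_groups = 1, max_groups = 3))
heads
#> <fragment_library> 6 unique fragments (from 8 graphs over 6 feasible of 10 selections)
#>   id            smiles                        selection n_nodes
#> 1 h1   *OS(=O)(=O)[O-]                dummyx1+sulfatex1       2
#> 2 h2  *COS(=O)(=O)[O-]  dummyx1+sulfatex1+methylidenex1       3
#> 3 h3 *CCOS(=O)(=O)[O-]  dummyx1+sulfatex1+methylidenex2       4
#> 4 h4                *O               dummyx1+hydroxylx1       2
#> 5 h5               *CO dummyx1+methylidenex1+hydroxylx1       3
#> 6 h6              *CCO dummyx1+methylidenex2+hydroxylx1       4

tails <- generate_all(group_set(list(
  group_spec("dummy", "*", 1),
  group_spec("hexylene", "CCCCCC", 2,
             connections = list(list(atom = 1, cap = 1),
                                list(atom = "final", cap = 1))),
  group_spec("methyl", "C", 1, max_occurrences = 2)),
  role = "tail", min_groups = 2, max_groups = 3, core_groups = "hexylene"))

cand <- assemble_library(heads, tails)
cand
#> <candidate_set> 6 candidates (6 heads x 1 tails), 100.0% valid
#>   head_id tail_id                  smiles valid rejection_reason
#> 1      h1      t1   CCCCCCCOS(=O)(=O)[O-]  TRUE             <NA>
#> 2      h2      t1  CCCCCCCCOS(=O)(=O)[O-]  TRUE             <NA>
#> 3      h3      t1 CCCCCCCCCOS(=O)(=O)[O-]  TRUE             <NA>
#> 4      h4      t1                CCCCCCCO  TRUE             <NA>
#> 5      h5      t1               CCCCCCCCO  TRUE             <NA>
#> 6      h6      t1              CCCCCCCCCO  TRUE             <NA>
```

The six candidates are the C7–C9 alkyl sulfates and fatty alcohols: each
head's `*` fused to the tail's `*` by one single bond. `generate_all`
reports how many selections were admissible (10), how many were feasible
(6) and how many raw graphs collapsed to unique molecules (8 → 6:
permuting the two methylene instances gives the same chain).

Property models train from `(smiles, value)` CSVs — see
`?train_qspr` and `?rank_candidates`; the config-driven pipeline
(`?surf_run`, with a thin CLI at `inst/cli/surfcamd.R`) chains
generation, assembly, training, prediction and optimization, writing
`pareto.csv` sorted by TOPSIS closeness.

The case-study input tables (14 head groups + dummy, 7 tail groups +
dummy, with chemically corrected SMILES and the original verbatim
strings side by side) ship in `inst/extdata/`, together with the two
optimization configurations.

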