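---
title: "Decomposition-based surfactant design: models and methods"
author: "surfcamd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposition-based surfactant design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfcamd)
```

## The design problem

Surfactants are amphiphiles: a hydrophilic head bonded to a hydrophobic
tail. Designing one computationally means searching an enormous discrete
space of molecular graphs for structures that balance performance
properties (critical micelle concentration, surface tension, Krafft point)
against environmental ones (aquatic toxicity, biodegradability) and
synthesizability. Monolithic formulations that couple structure generation
with property prediction restrict the property models to forms an
optimizer can digest. `surfcamd` instead decomposes the problem:

1. enumerate *all* feasible hydrophilic heads and hydrophobic tails from
   user-defined building-block groups (two independent generation
   problems);
2. assemble every head x tail combination into a full molecule and screen
   the finite library with data-driven QSPR models;
3. rank the pool by epsilon-constraint multiobjective enumeration, Pareto
   filtering and TOPSIS.

Because the candidate pool is finite and fully enumerated, the property
models can be arbitrary (here: linear models over 2D descriptors) without
complicating the optimization.

## The graph-generation model

A *group* is a molecular fragment (SMILES) with a declared number of free
attachment points, its valence $v_j$, and per-atom connection slots. A
fragment (head or tail) is a graph whose nodes are group instances and
whose edges are single bonds; double and triple bonds live inside groups,
never between them. One *dummy* group (`*`, valence 1) marks the
attachment point where head and tail will later fuse.

For a selected multiset of groups the model asks for all symmetric
non-negative integer matrices $y_{jj'}$ (bond multiplicities) with

* $\sum_{j'} y_{jj'} = v_j$ — every free valence is used (unused valences
  would be radical sites; hydrogen saturation is handled at the atom
  level, not by leaving graph valences open);
* $y_{jj} = 0$ — no self-bonds;
* $y_{jj'} \le 1$ when both nodes are multivalent;
* $y_{jj'} \le v_j - 1$ between a multivalent node $j$ and a
  single-valence node — a multivalent node may not spend all its bonds on
  one collapsed partner;
* for every subset $S$ of multivalent nodes with $|S| \le J_m =
  \lceil (m+1)/2 \rceil$ (where $m$ counts multivalent nodes):
  $\sum_{j,j' \in S} y_{jj'} \le 2|S| - 1$ — no short cycles or saturated
  subtrees among small subsets;
* $\sum y_{jj'} \ge 2(n-1)$ — at least a spanning tree's worth of bond
  endpoints.

All instances of a single-valence group of one type are *collapsed* into
one node whose valence is the instance count (four methyls become one
node of valence 4); each instance of a multivalent group is its own node.
Collapsing removes permutation-redundant solutions wholesale.

Two implementation notes on these constraints, both verified by tests:

* The subset constraints are equivalent to forbidding cycles of length
  $\le J_m$ in the subgraph induced by the multivalent nodes (a minimal
  violating subset is exactly a cycle; the symmetric sum counts each
  internal edge twice). The enumerator checks girth on that induced
  subgraph; the brute-force oracle in the fixtures module instead checks
  every subset sum literally, so the two routes are independent. Cycles
  *longer* than $J_m$ are genuinely admissible in this model.
* The spanning-tree bound is implied by valence saturation plus the
  connectivity filter. The oracle omits it entirely, and the
  oracle-equivalence tests confirm it never changes the feasible set.

### Exhaustive enumeration with integer cuts

The feasibility problem has a constant objective — the point is not an
optimum but the *set* of solutions. `enumerate_fragments()` performs an
exact depth-first search over the upper triangle of the adjacency matrix
with constraint propagation (per-pair multiplicity bounds, remaining-
valence pruning, row-completion checks). Each accepted solution is
recorded as an *integer cut* that excludes its exact bond-value pattern
from the remaining feasible space, so enumeration provably never repeats
a solution; with purely binary bond variables this cut reduces to the
classical support cut (two distinct binary solutions with equal row sums
can never have nested supports, but bounded-integer ones can — hence the
value-pattern form). Enumeration stops on exhaustion, with a safety cap
of 10,000 solutions per selection.

Connectivity is decided *after* feasibility by a breadth-first search
from node 1; the subset constraints above are necessary but not
sufficient, so the BFS is authoritative. Disconnected solutions are
discarded but still cut, so enumeration progresses past them.

One subtlety survives to the atom level: a collapsed single-valence node
can make the *collapsed* graph look connected while the expanded molecule
is not (one methyl instance bonded to the dummy, the others decorating a
ring elsewhere). Such graphs pass the BFS but are caught unambiguously at
assembly, where they produce multi-fragment SMILES (a `.`) and are
rejected. The shipped tail table produces 375 such graphs, all rejected.

### Selections and deduplication

`generate_all()` iterates over every admissible selection: the dummy
exactly once, core groups always included, per-group occurrence limits
$n_j$ respected, and the total number of chemical group *instances*
within the configured size bounds (the dummy does not count toward the
bounds — it is a placeholder, not chemistry; and instance counting
matches the "maximum number of groups" semantics of the occurrence
column). Selections whose total valence is odd are skipped — no graph
can saturate them.

Distinct selections, and symmetric instance permutations within one
selection, can yield the same molecule. The union is therefore
deduplicated by canonical SMILES of the *assembled* fragment, not by
adjacency matrix. The converse ambiguity also exists and is accepted: an
asymmetric group (an ester can face either way) makes one adjacency
matrix correspond to several constitutional isomers; the assembler
resolves it deterministically (below), so enumeration yields one
structure per adjacency matrix.

## From graphs to molecules

Each group's SMILES is parsed (through Open Babel) into an atom-level
bond matrix; hydrogens stay implicit, tracked as the gap between an
atom's standard valence (charge-adjusted: `[N+]` gains a bond, `[O-]`
loses one) and its explicit bond-order sum. Every unit of adjacency
multiplicity becomes one single bond placed at the next unused declared
connection atom of each group — slots are consumed in declared order,
neighbors processed in node-index order — consuming one implicit
hydrogen per endpoint. This is deterministic: rebuilding a graph always
gives the same molecule, and swapping same-group instance nodes (an
automorphism) provably cannot change it. Ring positions are honored
exactly; a para-disubstituted phenyl bonds at ring atoms 1 and 4, never
ortho or meta.

Head-tail fusion removes the two dummy atoms and bonds their former
neighbors. Sanitization then checks every atom against its allowed
valence set (C 4; N 3; O 2; S 2/4/6; P 3/5; halogens 1; formal charges
shift the set) and rejects multi-fragment structures; Open Babel itself
is permissive about hypervalent atoms, so this validation is the
package's own. Canonical SMILES are produced by Open Babel in batched
calls; an unparseable entry aborts the remainder of an Open Babel batch,
so failed entries are retried singly.

The shipped head and tail tables (`inst/extdata/`) carry both the
chemically corrected SMILES used by the package and the original
verbatim strings, which lost bond-order characters in typesetting; one
head group (the sulfinate) additionally needed its oxygen count fixed,
as no bond-order assignment of the verbatim string admits an attachment
at its declared connection atom. With these tables the package
enumerates 1291 unique heads (from 433 feasible selections of 1548
admissible) and 2353 unique tails (92 of 193) — counts the test suite
and the acceptance script recompute from scratch. These counts are
extremely sensitive to structural constraints: the tables encode only
what their columns can express (valences, connection atoms, occurrence
limits, size bounds, a mandatory core), and any further structural rule
would prune the space substantially.

## Property models

`compute_descriptors()` produces a numeric 2D descriptor block per
molecule: element and bond composition, ring and branching counts,
degree distribution, topological indices (Wiener, Zagreb $M_1/M_2$,
Randic, eccentricity statistics) and Open Babel physicochemical
properties (MW, logP, TPSA, molar refractivity, H-bond donor/acceptor
counts) — 34 descriptors in the current build. The exact count is
library-version metadata; the *protocol* downstream is the contract.

Filtering follows a correlation protocol: drop missing/non-numeric and
constant columns; build the graph of descriptor pairs with
$|r_{Pearson}| > 0.9$; remove outright any descriptor correlated with
more than two others; among surviving correlated pairs discard the
later-ordered member (ordering = the generator's canonical column
order, recorded in the model artifact). The "more than two others"
versus "pairs" reading of the rule is ambiguous; the implementation
applies degree-greater-than-2 removal first, then pair resolution, and
is idempotent by construction. On small descriptor blocks over
structurally homogeneous molecules this protocol can legitimately
remove everything — training then fails loudly rather than silently.

`train_qspr()` splits 80/20 at a fixed default seed (0), fits either
partial least squares (via `mixOmics`, component count chosen by the
user per property) or lasso with 5-fold cross-validated penalty (via
`glmnet`, folds derived from the same seed), and reports $R^2$ and RMSE
on both splits. The split is unstratified. CMC and LC50 are modeled on
the log10 scale, matching how such data are tabulated; predictions
return log values by default with a natural-scale option. Whatever the
family, the fitted predictor is reduced to an explicit affine function
(intercept + coefficients over named descriptors) — extracted exactly
for PLS by probing the fitted map at the origin and the unit vectors —
so predictions are reproducible from a two-file artifact (JSON
parameters + descriptor list) without the fitting libraries. A constant
response yields a flagged degenerate model that predicts the constant
($R^2$ reported as 0, undefined).

No pretrained coefficients ship with the package: the literature
training sets for these properties are not redistributable, so models are trained on user-supplied `(smiles,
value)` CSVs, and the test suite exercises the protocol on synthetic
data with known sparse linear structure. The synthetic generator
(`synthetic_qspr_dataset()`) draws independent standard-normal
descriptors — it emulates the *statistical shape* of a descriptor table
(dimensions, sparsity of the true signal, noise level), not the heavy
correlation structure or distributional quirks of real descriptor
blocks. Passing its recovery tests (support recovery across seeds at
$n = 200$, $p = 50$, $k = 5$, $\sigma = 0.1$) validates the training
protocol, not real-data predictive accuracy.

## Multiobjective ranking

Hard property cut-offs from the optimization table are applied first,
as a pre-filter. Among the remaining candidates the first-listed
objective is optimized by enumeration while each other objective is
bounded by a grid value: the observed range $r_i = f_i^{max} -
f_i^{min}$ is split into $q_i$ equal intervals (default $q_i = 10$,
hence 11 grid points, endpoints at the observed extrema), with bounds
$f_i \ge \varepsilon_i^k$ for maximized secondaries and the mirrored
$f_i \le \varepsilon$ for minimized ones. One winner is taken per
feasible cell — ties broken lexicographically on the oriented secondary
objectives, then by candidate id, for determinism — and the union over
all $\prod (q_i + 1)$ cells is Pareto-filtered (weak dominance by a
strictly better point removes a candidate; exact duplicates are kept
and flagged as ties).

TOPSIS scores the front: objectives oriented so larger is better,
max-min normalized per objective, equal weights; closeness
$= d^- / (d^+ + d^-)$ with $d^+$/$d^-$ the Euclidean distances to the
all-ones ideal and all-zeros negative-ideal. A candidate at the ideal
scores 1, at the negative-ideal 0; a front with zero range on every
objective degenerates to 0.5 everywhere, with a warning. The ranking is
invariant to affine rescaling of any single objective. The default
report length (`top_k = 4`) is a convenient shortlist size for
experimental follow-up, configurable.

## Degenerate inputs and numerical choices

* Odd-valence selections, valence-mismatched pairs, sub-2-node sets:
  empty enumeration, not an error.
* Degenerate objective range: single-point grid with a warning.
* All-infeasible epsilon cells: empty solution set with a warning.
* Enumeration cap 10,000 solutions per selection; brute-force oracle
  refuses above 7 nodes and 5e6 candidate matrices (it is a test
  oracle, not a production path).
* Descriptor filtering requires at least 2 molecules; training at
  least 10 and at least one descriptor column.
* All randomness (splits, CV folds, synthetic data, sampling) flows
  from explicit integer seeds; enumeration and assembly are fully
  deterministic, and re-running any pipeline stage with the same
  configuration reproduces byte-identical outputs.

## Interfaces and problem sizes

Configuration, group tables and optimization tables are CSV with the
documented column layouts (spreadsheets export to them losslessly);
fragment libraries are written as `.smi` plus CSV, candidate libraries
as `candidates.csv`, ranked results as `pareto.csv`, and every pipeline
stage appends counts to a machine-readable `run_summary.json`. The test
suite enumerates the full shipped head and tail problems (1548 and 193
selections) and measures assembly validity on seeded samples of a few
thousand head x tail pairs — large enough for a stable rate on a
library whose assembly is valid by construction.

## Known limitations

* No rings *between* nodes: cycles exist only inside groups, matching
  the single-bond internode convention. No stereochemistry (the
  glycoside's stereocenters are dropped).
* One structure per adjacency matrix: constitutional isomers that
  differ only in the orientation of an asymmetric group are represented
  by the orientation the deterministic slot rule picks.
* The 2D descriptor block is compact; properties dominated by
  conformation (interfacial behavior in particular) are outside what
  linear models over it can capture.
* Head/tail counts are properties of the group tables plus the
  constraints the table layout can express; richer structural rules
  (position-specific exclusions, composition rules beyond a single
  core) would need new columns and constraints.
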